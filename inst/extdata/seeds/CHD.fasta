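>CHD_01
VWGCSYIKRINGPHDRDGFPWWIKANFPSGIAYANTSPNDGSVIHRHVSA
>CHD_02
VWGCSYIKRINGPHDRDGFPWWIKANSPSTYAYANTSPNDGSVIHRHVSA
>CHD_03
VWGCSYIKRINGPHDRDNFPWCIKANFPSQIAYANTAPNDGSVIHRHVSA
>CHD_04
VWGCSYIKRINGPHDRDGFDSWEKANFPSGIAYANASYNDGSVIHRHVSA
>CHD_05
VWGCSYIKRIKGEHDRDGFPWWIKANFPSGIAYAPTSPNDGSVISRHVAA
>CHD_06
VYGCSYIKRINGPHDRDFFPSCIKANFPSGILYANTSPNDGSVIHRHVSA
>CHD_07
VWGCSYIKRINGPHDRDGFPWWIKANFPSGHAYANTSPNDGSVIHRHVSA
>CHD_08
VCGCSYIKRWNGPHDRDGFPFWIKANFPSGIAYANTSPNDGSVIHRHVSA
>CHD_09
VWGDSYIKLINGPHDREGFPWWIKVNFPSGIAYANTSPADGSVIHRHVSA
>CHD_10
VWGCSYIKRCNQPHDRDGFPWWIKANFPSGIAYANTSPNDGSVIHRFVQA
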