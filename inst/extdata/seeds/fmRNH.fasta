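>fmRNH_01
EHIQAPWHHDAHRLMSNWYFPYCGLRQIYCIIDANYFNINLWIWEKAEICYRNDLWQGVFAIFVCRGMKDIIKTYNKPYDENCEWPAQCEWTWSWAEDRHANVRPLNWSHWFGWFGFINRWHWVSLPVFDSGYWIKMQKD
>fmRNH_02
EHIQAPWHHDKGRLMSNWYFPYCGLRQIYCIIDANYFNINLWIWEKAEICYRHDLWQGVFAIFVCRGMKDIIKTYNKPYDENCEWPAQCEWTWSWAEDVHANVRPLNWSHWFGWFGFINRWHWASLPVFDSGYWIRMQHD
>fmRNH_03
EHIQAPWHHDMARLMSNWYCPYCGLRQIYCILDANYFNINLWQWEYAEICYRNDNWQGVFAIFVCRGMKDIIKWYNKPYRENIEWPAQCEQTWSWAEDRHATVRPLNWQHWFGWFEFINPWKWVSPPVFDSGYWIKMEKD
>fmRNH_04
EHIQAPWHHDAHRLMSNWYFPYMGLRQIYCIIDANFFNINLWIWEKAEICYRNDLWQGVFAIFVCRGMKDIIKTYNKPYLRNCEWPAQCEWTWLPAEDRHANVHPLNWSHWFGWFSFINRWHWVSMPVFDSGYWIKMQKD
>fmRNH_05
EHIQCPWHHDAHRLMSNWYFEYCGVRAIYCIIVAPYFNINLWIWEKAEICYLNDLWQGVFAIFVCRGMKDIIKTYNKPYDENCEWPAQCEWTWYWAEDRHANVRPLNWSHWFGWFGFYNRWHWVSLPVFDFGYHIKMQKR
>fmRNH_06
EHIQAPWHHDAHRLMSNWYFYYCGLRQIYCIIVANYFNINLWIWEKAEICFRNDLWQGVGAIFVCRGMKDKIKTYNKPYDENCEWPAPCEWTWSWAEDVHANVRPLNWSHWFGWFGFINRWHWVSLKVFDSGYWIKMQKD
>fmRNH_07
EHIQAPWHHDAHRLMSNWYFPYCGLRQIYCIWDANYFNINCWIHEKAEICYRFDLWSGVFAIFVCRGMKDIIKTYNKPADENCEWPAQCEWTWGWLEDRHANVFPLNWSHWFGWFGFINTWHWVSLPVFDAGYWIKPQKD
>fmRNH_08
EHIQAPMHHDAHRLMSKWEFPKCGLRQLYCIIDANYFNINLWIWEKAEICYRNDLWQGVFAIFVCRGMKDIIKTYNKPYDENCEWWALCEWTWSWAEDRHANVRPLNWSHWFGWFGFINRWHWVSLPVPDSGYWIKMNND
>fmRNH_09
EHIQAPWHCDAHRLMSNWYSPYCGLRQIYCIISANYFNINLWIWEKAEICYRNWLWQGVFAIFVCRGMLDIIKTYNKPYDENSEHPAQCEWTWSWAEDRHANMIPLNWSHWFFWFGFINRWKWVSLPVFDSGYWIKSQKD
>fmRNH_10
EHIQAPWEHDVHRLMSNWYFPYCGLRQIYCIIDRNYFNINLWIWEKNEICLRCDLWQGVFAIFVCRGMKDILKTYNKPYDENCEFPAQCEWTWSWAEDLRANVRPLNWSHWFGWFGMINRWHWVSLPPFDSSYWIKMQKA
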