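>RT_LTR_01
DIGMEYSMGLKRCIPQKAGNRQVLVWVCYCWVKLSSEGHQEVYEKFLGMCVMCANFLEASDQDWFETEEIDGACSFQRSAKQWDVEAFGIWIRNAEKVVGKIGPAMMYFMMLWWNHGDVIPCYAKFPRMVGNKIDTTETFPILILEEGEYVDDHWDGQEEYNCWSRVPMYQWDGMYHKKYPNANKLTILKITCEPRGMLMLIGESQCELECVFRHMAMADDLQPVHRESTDVKNDKHCDP
>RT_LTR_02
NIGMEYSCGLKLCIPQKAQNRQVLVWDCYCWVKLSSEGHQEHYEKFLGMCVMCANFLEASDQDWFETEEIDGACSFQRSAKQWDVEAFGIWIRNAEKVVGKIGPAMMYFMMLWWNHGDVIMCYAKFPRMVGNKIDTTETFHILILEEGEYVDDHWDGQEEYNLWSRVPMYQWDGMYHKKYPAANKLTILKITCEPRNMLMLIGESQCELECVFRHMAMADDLQPVPRESTDVKNDKHCDP
>RT_LTR_03
DIGMEESMGLKRCIPQKAGLRVVLVWVLKWWVKLSSEGHQEVYCKFLCMCVMVANWLEASDQDWFETEEIDGACSFQRSAKQWTVTAFGIWVRNAEKVVGKIGPAPMYFMMPWWNHTDVIPCYAKFPRMVGNKIDTTETFPRLILEEGEYVDDGWEGQEEYNCWSRVPMYQWFGMYHKKYPNANKLSILKITCEPRGMLMLIGESQCELECVFRHMAMHDDLQPVHRESTDVKNDKHCDP
>RT_LTR_04
DECMEYSMGLKRCIPQKAGNRQVLVHVCYCWVTLSSEGHQEVYEKFLGMCVMCANFLEASDQDFFMTEEIDGACSFQRSAKQWDVGAFGIWIRNAEKVVGKIGPAAMYFMVLWWNHGDVIECYAKFPRMVGNKIDNTETFPILIGNEGEYVDDHWDGQNEYNCWSRVPMYQWDGMYHKKYPNANKLTILKITCEPRGMLMLIGESQCELECVFRHMAQADDLQPHHRMSTDVKNDKHCDP
>RT_LTR_05
DIGMPYSMGLKRCIPQKAYNRQVLVWVCYCWVVLSSEGHQEVPEKFLGMCVMCANFLEASDQDWMETEEIDGACSFQRSAKQWDVEAFGIWIRNAEKVVGKIGPAMMYFMMLWWNHGNVIPCYAKFPRMVGNKIDTTETFPILILEEGEYVDDHWKGQEEYNCWSRVPMYQWKGMYHKKYPNANKLTTLKITCEKRGMLMLIGTSQCELECPFRHMAMAMDLQPVWRESTMVKMDKHCDP
>RT_LTR_06
DIGMEISWGLKRCIPQKPGNRQVIVWVCYCWVKLSSEGHQEVYEKFLGEVVMCANFLEASDQDWFETEEIDGACSSQRSAGQWDVEAFGIWIRNAEKRVGKIGPAMMYFMMLWWNHGDVHPCPAKFERMVGNSIDTQETFPILILWEGEYVDDHWDGQEEYNCWSRVPMYYWDGMYHKKYPNANNPDILKITCEPRGMLMDIGESQCELECVFRHMACADDIQPVHRLSTDVKNDKHCDP
>RT_LTR_07
DICMEYSMCLKRCEPQKAGNRQVLVWVCYCWVKLSSEGWQEVYEKFLAMCVMYANFLEASDQLWFETEEINGACSFQMSAKAWDVEKFGIWIRNAEKVVGKIGRAMMYFMMLWTNHGGVIGCYAKFPRMVGNKIDTTETFPILILEETEYVDDHWDGQEEYNCWSRVPMYQWDGMYHKKYPNANFLTILYPACEPRGMLMLIGESQCELECVFRHMAMADDLQPVHRESTDVKNDKHCDP
>RT_LTR_08
DIGMEYSMGLKRCIPQKAGNRQVLVWFCYCWVKLSSENHQEVYEKFLGMCVMCANCLEASDQDWFETEEIDGSCSFQRSAKQWDVEAFGIWIRNAEKVVGKIGYAIMYFMMLWWNHGDVIPCYAKFPRMVGNKIDTTETFPILILEEGEYVDDGWDGQEGYNCSSRVPMYQWYGYYHKKYPNANKLTILKITCEYRGMLMLIGESQCELSCVFRHMAMADDLQPVHRESTDVKNDKHCDP
>RT_LTR_09
DIGMEYSMGLKRCIPQKAGNRQILVWVCYCWVKLSSEGHQEVYEKFLGMCVMCANFLEASDQDQFETEEIDGACSFYRSAKQWDVEAFGIWIRNAWKVVGKKGPATMYFMMLWWNHGDVIPCGAKFPRMVGNKIDTTETFPILILEEGEYVDDHWDGQEEWNCWSRVPMYQCDGMYHKKYPNANKLTILKYTCEPRGMLMLIGESQCELECVFRHYAMYDDSQPVHRESTDIKNDKHCYP
>RT_LTR_10
DIGMEYSMGLKRCIPQKAGNREVLAWVCYCWVKLSSEGHQEVYEKFQQMCVMCANFLEASDQDMFETEEIDGACSFQRSAKQWDVEAFGIWCRNALSVVGKIGFAMMYFMMLWWNHGDVIPCYAKFPRMVGNKIDFTEDFPIVILEEGEYVDDIWDGQEEYNCWSRVYMYQWDGMYHKKYPNANKLTILKITCEPRGMLMLIGESQCPLVCVFRHMEMKDDLQPVHRESTDVKNDKHCIP
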