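>RT_nonLTR_01
SWCTRLSATLWAWKNATECIVSRDVTMNHRFWRNFVQCAIDEHNICPLNIIEMICLYSDCCQVALMTLMHIAIYSDRIIDFCDMKWVIQVKNKKYSWYGKAPNPLNVQCYMFQAQFLFDKIANIGTEFVKGIMKFRAFARSYDVFVWAFYVDDQPHQFSMDIEDYKTYTFDPMVCMNHPKVFREAYSENEGTSEHANWCRSQPATYYVVQYASQKSHIQEKQPLAQQIMKGRIIAQDPQKIEVMLRMYWMPLFVYSLHNF
>RT_nonLTR_02
CWCTRLSPTLWAWKNATECIVSRDVTMIHRFWRNWEQCAIDEHNICPLNNIEMICYYSDCCQVALMTLMHIAMYSDRIIDFCDMKWVIQVKNKKYSWYVKAPNPLNVQCYMFQAQFLFDKIANIGTAFVKGTMKFRAFARGYDVFVGAFYVDDQPHQFSMDYIDYKTYQFDPMVCGNHPKVFREAYSENEGTSEHANWCRSQPATYYVVQYASQKSHIQEKQPLAQQIMKGRIIAQDPQKIEVMLRMYWMPLFVFSLHNF
>RT_nonLTR_03
SWCTRLSATLWAWKNATECIVSRDVTMNHRFWRNFVQCTIDEHNICPLRIIEMIELYSDCCQVALMTLMYIAIYSDRIIDFCDMKWRIQVKNKKYWWLGKAPNPLNVQCYMFQAQFLFDKIALIGTEFVEGIMKFRAFARSYDVFVWAFYVDDQPHQFSMDIEDYKTFTFDPMVAMNHPKVFRESYSENEGTSEDANWCRSMGATYGVVQYASQKSHIQEKQPLPQQIMKGRIIAQDPQKAEVMLRMYWMPLFVYSLMNF
>RT_nonLTR_04
SWCTRFRATLWAWKNATECIVSRDVTMNMRFWRNFYQCAHDHHNIFVLNIIEMICLYSDTCQVALMTLMHIAIYSDRIIDFCDMKWVPQVKNKKYSWYGKAPNPLNVQCYCFQAQFLFDDIANIGTEFVKGIMKFRAFARSWDVFVWAFYVDDQPHQFSMDIEDYKTYTFDPMVCMNHPKVFREAYSENEYTSEHANKCRSQPATYYVVQYAPQMSHIQEEQPLAQQIMKLREIAQDPQKIEVMLRMYWMGLFVYSLHNF
>RT_nonLTR_05
SWCSRLSATLWAWKNATECIVSRDVTMTHRFWRNFVNCAIDEHNICPLNIIEMICLYSICCQVTLMTLMHINIYSDMIEDFCDMKWVIQVKNKKYSWYGVAPPPLNVQCYMFQAQFLFDKIANIGTEFVKGIMKFRAFARSYDVFVWAFYVDDQNHQFSMDIEDYKNYTFVPMVCMNHPKVFREAYSEMAGTSAHANWCRSQPATYYVVQYASQKSHIKEKQPLAQQIMKGRIIAQDPQKIEVMLLMYWMELFVYSWHNF
>RT_nonLTR_06
SWCTRLSATLWAWKQAMECIVSRDVTMNHGFWRNFVQCAIDEHNIRPLNIIEMICLYSDCCQVALMTLMHIAIYSDRIIDFCDMEWVIQVKNKKTSWYGKAPNPLNVQCYMFQAQFAFDKIANIGTEFVKGIMKFRAFARSYDVFVWAFYVDDQPHQFSMWIEDYKTYTFDPMVCMNHPKVYREAYSENEGTSEHYNWCRSQPATYYVVQYASQDSHIQEKQPLAQQIMKGRIIEQDPQKIEVMLRMYWMPLFVYSLHNF
>RT_nonLTR_07
SWCTRLSATLWALKNATECIVSRDGTMNHRFWRNFVQCAIDEHNICPLNIIEEICLYSDCCQGALMTLMHIAMYSDRIIVFCDMGWVIQYKNKKYSIYGKAPNPLNAQCYMGQAQFLDDKIANIGTEFVKGIMKFRAFARVYDVFVWAFYVDDQPHQFSEDIETYKTYTFDPMVCSNHPKVFREAYSENEGESEHAKWCRSWPATYYVVQYASQKSHIQEKQPLAQQIMKGRIIAQDPQKIEVPLRMYWMPLFVYSLHNF
>RT_nonLTR_08
SWCTRLSATLWACKNATECIVSRDVTMNHYFWRNFVQCAIGEHNICPLNIIEMICLYSDCCQVASMTLMHIAIYSDCIIDKCDMKWVIQVKNKKYSWYGKAGQPLNVQCYMMQAPFLFDKIANIMTEFVKGIMKFRAFARSYDVTVWAQYVDDQPHQFSMDGEDYKTYTFDPMVCMNHPKVFREAYSENEGTSEHANWCRNDPATYYVVQYASQPSHIQETNPLAQQIMKGRINAQDPQKIEEMLFMYWMPWFVYSLTNF
>RT_nonLTR_09
SCCTRCSATLWYWKNATECIVSRDETMNHRFWRMFVQCAIDEHNICPINIIEQRCLYSDCCQVALPTLMHIAIYSDRIIDFCDMKWVIQVKNKKYSWYGKAPNPLQVQCYMFQAQFLFDKIANIGTFFVKGIMKGRAFARSYFVFVWAFYVDDQPHQFSMDWEDYKTYTFDPMVCANHPKVFREAYSENEGTSEHANWNRSQPATYYVVQYASQKSRIQEKQPLAQQIMKGKIIAQSFQKIVVMLRMYWMPLFVYSLHNF
>RT_nonLTR_10
SWCTRLSATLWAWKNPRECIVARDVTGNHRFWRNFVQCAIDEHDWCPLNIIEMECLYSDCCQVILMTLMHIAIYSDRIIDFCDMKWVIQVKNKKYSWYYKAPNPLNVQCYMFQAQFLFDKIANIGTEFVKFIWKFRAFARSYDVFQWAFYVDDQPHQFSMDIEDYKTWTFDPMVCMNHPKVFRPAYEENEGTSEHANWCQSNPATYYVVQYADQKSHIQEKQPLAQQIMKYRKIAQDPQKIEVMKRSYWMPLFVYSLHNF
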