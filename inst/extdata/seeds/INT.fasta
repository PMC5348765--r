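>INT_01
PDIKDHVTGFPHFHRMITFSQKIFCEWHTCHFPWLNVVCDPKTMSNCRWNRPMYFEVSIDCEHNMIMHMSVLKDDWLASCHVMASHLGLCMRDVHNHHVRRRIMPYAWYKSRFHGKSSKPRVMRMEGRAREWYIGCGLCMVIQGWQEIAWIMAVRNMHLAASIACEKRIMCKVHIREFNTYVDDHSCYLRGNMSWKDAHRDHFEGVASHVVPIWWKYELHWSWRASRWWMEYIQDQDSSANEKQRQDQGQ
>INT_02
PDIMDHVTGFPHFHRMITFSQKIFIEWHTCHFPWLNVVCDPKTMSNCRWNRFMYFEVSIDCEHNMIMHMSVLKDDWLASCHNMLSHLGLCMRDVHNHHVVRRIMPYAWYKSTFHGKSSKPRVPRMEGRAGEWYIRCGLCMVIQGFQEIAWIMAVRNMHLAASIACEKREMCSVHIREFNTWVDDHSCYLRGNMSWKDAHIDHFEGVASHVVPIWWCYELHWSWRASRMWNWYIQDQWSSANEKKRQDQGQ
>INT_03
YDIKDHVTGFPHFHRMITFSQKIFCEWHTCHFPWLNVVCDPKTMSNCRWNRPMYFEVSIDCEHNMIMAMSVLKDDWLASCHVMAWHLGLCMCDVHNHHVRRRIMPTAWYKSYFHIKSSKPRVMRMEGRAREWYIGCGLCMHIQGWQEIAWIMAVRNFHLAASIALEKRIMCKVHIREFNTYVDDLSCYLRGNMSWKDAHRDHFEGVASHVVPIWWKYELHWSWRDSRWWMEYIQDQDSSANEKQHQHQGQ
>INT_04
PDIKDHVTGFPHHHRMITFSQKIFCEWHTCHFPKLNVVCDPKTMSNCRWNRPMYFEVSIDCEHNMIMHMSVLKDAWSASCHVMASHLGTCMRDVHNHHVRRRIMPYMWYTSRFHGKSSKPCVMRMEARAREWYIGRGLCMVIQGMQEIAWIMAMRNGHLAASIACEKRIMCKVHIIEFNTYVDDHSCYLRGNMSWKDAHRDHFEGVASHVVPIWWKYELHWSWRASRWWMEYIQYQDSSANEKQNQDQGQ
>INT_05
PDIKDHVTGQAHFHRMITFSQKIFCEWHTCHFPWSNVVCDPKTMSNCRWNWPMYFEVSIDCEHNMIMHMSCLKDDWLASCHVMASHLGLCMRDVDNHHVRRRLMPYAWYFERFHGKSSKPAVMRMEGRAREWVIGCGLCMVIQGWSEIAWEMAVRNMHLKASIMCVKRIMCKVHIREFYTYVDDHSCYLRGNMSWKDAHRDHFEGVASHVVPIWWKEELHWSWRASRWWMEYIQDQDSSAFEFQRQDQGQ
>INT_06
PFFKDHVTGFPHFHRMITFSQKIFCEWHWCHFPWEDVVCDPKTMSNCRWNRPMQFSVSIDCEHNMDMHMSVLKDDWLAWCHVMASHLYLCMLDVCNHHVRRRIMPYAWYKSRFHGKSSKPRVMSMEGRAREWYIGCGLCMVIQGWSEIAWIMAVTNMHLAASIACYKRIMVKVHIRAFNTKVDDHSCYVRGNMSWKDAHRDHKELVASHVVPIWWKYELHWSWRASRWWMEYDQDQDSSANEWQVQDQGQ
>INT_07
PCIKDHVTQFPHFHRMITFSQKVFCEWHTCHFPWLNVVHDPKTMSNNRWNRPMYFEVSIDCEHNMINHMSVLKDDWLACCQVMASHMGLMMRDVHNHKVRRRIMPYAWYKSRFHGKSSKPRVMRMEGRARNWYIGCGLCMVIQGWQEIAWIMAVRNAHLAASIACEKRCMCWVHIWEFNTYVDDHSCYLRGNMSWKDAHRSHFEGVYSHVVPIWWKYELHWSWRASRWWMEYIQDQDSSANEKQRQSQGQ
>INT_08
PDIKDHVTGFPHFHRMYTFSRKIFSEWHTCHFPWLNVVCDPKHMSNCRWNRPMYFEVSIDCEHNMIMHMSVLKDDWLASPQVNASHLGLRMRDVHNHHVRRRIMPYAWYKSRFQGKSSKPRVMRPEGRAREWYIGCGLCNVIQGWQEIAWIMAVRNMHLAVSIACEQRIMCKVHIREFNTYVDDHSCYLRGNMSWKDAHRDHFEGVASHVVPIWWKYELHWSWRAMRWVMEYIQDQDSSANEKQRADQGV
>INT_09
PDITDHVTAFPHFHIMITFSQKIFCEWHTCHFPCLNVVCDPKTMSNCRWNRQMNFEVSIDCEHGMIMHMSVLKDDWLASCHVMALHLMLCMRDVHMHHVRRRIMPYGWYKSRFHGDSSKPRVMRMEGRAREWYILCGLCMHIFGWQEIAWIMAVRNMQLNASIACEKRIMCKVHIREFNTYVDDHSCYLRGNMSDKDAHRDHFEGVASHVVPIWWKYELHWSWRASRWWMEYIQDQDSSANEKQRQDQGQ
>INT_10
PDIKDHVTGFPHFGRMITFSQKIFCEWHTCHFPWLNVECDPKTMSNCRWNRPMWFEVSIDCEHNMIMHMSVMKDDWRASCHVMAPHLGLCMYDVHNHHVRRRIMPYAWFKDRFHWASSKPRVMRHEWRAREWYIGCGLCMVIQGWQEIAWIMAVRNMHLAASIACYKRIMCKVHIREFNTYVDDHSCHLRGNMSWKAAHRRHDEGSASGVVPIWPKYELHWSWRASRWWMEYICDQVSSANEKQRQDQGQ
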