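>gRNH_01
AKETEGKRPNSEKISTCHEDFLFHNCLIITCYKYRDPWGNCKWMQLWNHHIQDKMCLFQTRCLGYYEEVSMKPRCLAHQAPGEEWGNRASFEWRCEFGAHWKFKVMIFHKMMQYADLCWMPQPFEWCMET
>gRNH_02
AKETEGKRENEEKIEINCEDFLFHNELIITNYKYRDPWGNCKWMQLWNHHIQDKMCLFQTCGLIYYEEVSMKPRCLAHQAPGEEWGVRASFEWRNEFGAHWKFKVMIFHKMMQYADLCWMPAPFEWMMET
>gRNH_03
AKETEGKRPNSEPISGCHEDFLFHNCLIITCYKYCDPWGNCKWMQLWWHHIQDKMCLFQTRCLGYYEEVSMKPRCLAHQAPGEEWGNRASYEWRCEAGAHWKFKVMIFHKMMQYADLIWMPQPFEWCMET
>gRNH_04
AKETEGCRPNSEKISTVFEDPLFHNCLIYRCYKYRDPWGNCKWMQLWNHGIQDKMCLFQTTCLGYYEEVSMKPYCLAHQAFFEEWGNRASYEWRCEFGAHWKFKVMIFHKMMQYADLINMPQPFEWCMIT
>gRNH_05
AKETEGKRPNSEKISTCHEDFLFHNCLIITCYLYRDPWGNCKWMQLWNHPIQDKMCLFQTRCYGYYEEVSMKPRCLAHQAPGEEWGNRASFEWRCEFGAHEKFKAMIFHKMMQYDDDCWMPQPFEWCMET
>gRNH_06
AKETEHKRPNSEKISTCHEDFLFHNCLIITCYKYRDPWGNCKWMQLWNHHIQDKMRLFQGRCLGYYEEVSMKPRCLAHQAPGEEWGNRASFEWRCEFGAHWKFKVMIYHKMMQYADLCWMEQPFENCMET
>gRNH_07
AKETEGKRPNSHKISTCHEDFLFHNCLIITCYEYRDPKGNCKWMQLWNHHFQDKMCLFQTRCLGYYEDVSMKPRCLAHQAPGEEWGNRASRMWRCEFGPHWKFNVMICHKMMQYADLCWMPTPFEWCMET
>gRNH_08
AKETEGKRWNIEKISTCIEDFLFHNCLIILCNKYRDPWGNCKWMQKWNHHIQDKMCLFQTRCLGPYEEVSMKPRCLNHQAPGQEWGNRANFEWRCEFGAHWKFKVMIFHKMMTYADLCWMPQPFEMCMET
>gRNH_09
AKEAEGKRPNSRKISTCHEDFLFHNCRIITCYKYRDPWGNCKWMQLWNHHIQDKMCLFQTGCLGYYEEVSMKPRCLDHQAPGEEWGARASFEWRFEFPAHWKFKVMIFHKDMQYADLCWMPQPFEWCMET
>gRNH_10
AKETEGKRPNSEKISTCHEDFLFHNCLIITCYKYRDPWGNRKWMQLWNHHIQDKTCLFQTNKLEYYEEVSMKPRCNAHQAPGEEWGNRASFEWRPEFGAHWKFKIMIFHKMMAIADLCWMPQPNEWCQET
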