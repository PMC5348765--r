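>aRNH_01
HKYAVKSSTDSAIFPAQSQMARENLKRFDMWEIMCNNPFICDPVEGHHINTLVLQCCLPSEMQGWRGPMDRGGQNMLLQLEIAPEEYKILYMQAGQITGDHHTLDQEQDRMRYDRHEPQPGYPFAAIMADVTNRYDDFWE
>aRNH_02
HKYAVKSSTDDAIFPAQSQMARENLKRFDMWEIMCNDPFICDRVEGHHINTLVSQCCPPSEMQGWRGPMDRTGQNMLYQLEIAPEEVKILYMQAGQITGDHHTNDQIQDRMRYDRHEAQPGYPFAAISADVTNRYDDFWE
>aRNH_03
HKYAVKSSTDIAIFPAQSQMARENLKRFDQWEIMCNNPFICHPVESHHINTLVLQCCLPSEMQDWRGPMDVGGQNMALQLEIAPEEYKILYMQAGQITGDHHTLDQEQDRMVYDPHEPQPGYPFAAIMADVTLRYDDFWE
>aRNH_04
HKYAVKSSTDFAIFPAQSQWARENLKRFDMWEIMCNNPFICDPVEGHHINTLVLQCCLPSAMQGWRGRMDRGGQNMLLQLEIAPEEAKILYMQAGQITGDEHTMDQEQDRMRYDRHEPHPGYPFIAIMADVTNRIDGFTE
>aRNH_05
HKYAVKSSTDSQIFPAQRQMARENMKRPDMWEIMCNNPFICDPVEGGHINTLVLQCCDPSEMTGWRGKMDRGGQNMLPQLEIAPEEYKILDMQAGQITGDHHTLDQEQIRMRYDRHEPQPGYPFAAIMADKTNVYDDFWE
>aRNH_06
HKYVVKSSTDSAIFPAQSQMARENLKRFDMWEIMCNNPFICDPVEGHHINTLVLQCCLPSEMQGWRGPMDRGGQNLLLQLEIAPEEYKILYDQAGQRTGDHHTLDQEQDRMRYDRHEPQPGYPFAAILADVTNRYDDVWE
>aRNH_07
HKYAQKSSTDSAIFPAQSQMARENLWRFDMWEIMCQNPFQLDPVEGHHINTLVLQCCLPSEVQGWRGPMDRGGQNMLLQLEIAPEEYKILYMQAGQITGDHHTLDQEQDRMRYNRHEPQPGYPFGAIMADVTNRWDDFWE
>aRNH_08
WKYAVKSSTDSAIFPAQSQMKRENLKRFDMWEIMCNNPFICDPVEGHWINTTRLQCCLPSEMQGWEGFMDRGGQNMLLQLEIAPEEYKILYMQAGQITGDHHTLDQEQDRNRYDRHEPQPGYPFAAIMADATNKYDDFWE
>aRNH_09
HKYAVKSSTDSAIFEAQSQMARENLKRFPMWEIICNNPFICDPVEGHHANTTVLQCCLPSEMQSWRGPMDRGGQNMLLQLWIAVEELKRYWMQAHQITGDHHTLDQEYDRMYYDRHEPQPNYPFAAIMADVTNRTDDFWE
>aRNH_10
HKYAVKSSTDSAIFPAQSQRARENLKRFDMWEIMCNNPFICDPVEHHHINILVLQCCLPSEMQGARGPMDRGGQHQLLQLEIAPLEEKILYMQAGQIMGGHMTPDAEQDRMRDDRHEPQPGYPFAAIGADVTNRYDDFWE
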