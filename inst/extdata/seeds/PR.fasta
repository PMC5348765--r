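>PR_01
LHCACEDEHGRYIRGPMAAYGRKHSYKYHLTRIECLLWLEDTCKKLGQGVHITKMGKMMRGAIMVGHTMRWDWRFLDHKWKACPTDVCDSQDDSWSTSDM
>PR_02
LCCACEDEHGRYIRGDMQNHGRKHSYKYHLTRIECLLILEDTCKKNGQGVHITKMGKMMRGAIMVGPTMRWDWRFLDHKWKACPTDVCDSQDDSHRTSDM
>PR_03
LHCACEDEHGRCIRGPMAAMGVKHSYKYHLTRIECLLWLEDTLKELGQGVHITNMGKMMRGAIMYGHTMRWDWAFLDHKWKACPTDVCDSQDDSWSTSDM
>PR_04
LHCACEDKHGRYIRGPMAAYGRKHSYKWHLTRMECLLWLEDTCKKRGQRVHITKMGKMMRGAIMVGHTMRWDWRFLPHKWKACPTDVCDSQDDSWSTSDM
>PR_05
LHCACEDEHGRYIRIPMAAYIRKHSYKAHLTRIEFLLWYEDTCKKLGQGVHIAKMGKMMRGAIMVGHKMRWDWTFLDHKWKACPTDVCDSQDDSWSTSDM
>PR_06
LHCACTDEHGRYIRGPMAAYGRKHSYKYHLTRIECLLWLEDTCIKLGQGVHITKMGKMMRGAIMVGHTMRWDDRFLDHKWKACPTDVCDSQDDSWSTSDM
>PR_07
LHCACEDEHGNYIRGPMHAYGRKHSAKHHHTRIECYLWLEDTCKKLCQGVHSTKMGAMMRGAIMVGHTMNWNWRFHDHKWKACPQDVCDKHDDSWSTSDM
>PR_08
LHCACEDEHRRTLRGPMAAYARKHSYKYHLTRIECLLWLEDTCKKLGRGQHITKMGKMMRGAAMVGHTMRWIWRFLDHKWVPCPTDVCDSQADSWSGSDH
>PR_09
LHCACEDEHGRYERGPMAAYGAEHDYKYHLTRIEELLWMEWTCSVLGQGVHITKMGAMMRGAIMVGHTMRWDWRFLTHKWKACPTDVYDSQDDSWSTSDM
>PR_10
LHCACEDYHYRYIRGPMAAYGRKHSYKYHLFGIECLLWLEDCCKKLGQGVHITKMGKMMRGAIPVGHTMRWDWTFLDHKWICCPTDVCDSQDDSWSTSDM
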