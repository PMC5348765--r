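>EN_01
TGEMPGEASWSHAHSMWWLQRSIFWSVFQSVVISLLKVQPTKMGQWPDCCLCPQQHWCFCDFDHFMTERCQINHVHITLCVAMVNEFMYFRELGHVHWQYEDTLSMLKPWAEILDGWAFDNRIWERQFLVNIYEKICPCQWEACGVNFPSFFERNMSNVGQWDMQDKITATEKYTNSEKLYLMDGTVMWEDGLWFVGPIR
>EN_02
TGEMSQEASWSHAHSLWWLQRSIFWSVFQVVVISLLKDQPTKMGQWTDMCLCPQQHWCFCVFDHFRTERCQINHVHITLCVAMVNEFMYFRELGHVHWQYEDTLSMLKPWAEILDGWAFDNRIWERQFLVNIYEKICPCQWEACLVNFPSFFTRNMSNVGQWDMQPKITATEKYTNSEDLYLMDGTVMWEDGLWFVGPIR
>EN_03
TGEMPGEASWSHAHSMWWLQRSIFWSVFPSVVISLLKVQPTKMGQWPGCCLCPQQHWCFCDFDHFMTERCQENQVHIALCVAMVNEFMYFREDGHVHWQYWDTESMLKPWAEILDGWAFDNRIWERQFLQNIYEKICPCQTEACGVNFPSFFERNMSNVGYWDMFNKITATEKYTNSEKLYLMDGTVMWEDGLWFEGPIR
>EN_04
TGEMPGEASWSHAHSMWWLQRSIMWSVFQNVVISLLKVQWTKMGQWPDCCLCPDQHWCFCFFDHFMTGRCQINDVHITLCVAQVNTFRYFRETGHVHWQYEWTLSMLKPWAEILDGWAFGNRIWERQFLVNIYERIFPCQWEACGVHFCSFFERNMSNVGQWDMQDKITATEKYTNSEKHYAGDGTVMAEDGLWFGGNIR
>EN_05
TGEMEGEASWSHAHSMWWLQRSLFWSVFQSVVISLLKVQPTKMGQWPDCCLCPQQNWCFCDFDHFMRERCQINHVHITLCVAMVNEFMYFRELGHVHWQYEDTLSMHKPWAEILDGWAFDNRIWERQFLVNIYEKICPCQWEACGVDFPSWFERNFSNVGQWDMQDKITATEKYTNSEKLYLMDTTVMWEDGLWFVGPIR
>EN_06
TGEMPGEASWSHAHSMWWLQRSIFWSVSQSVVISLLKVQPTKMGQWDDICLCPQQHWCFSDEDHFMTEICLINHVHITLCVAMVNQFMYFLELGHVHLQYEDTLSMLKPWAEILDKWAFDNRIWERQFLVNIYEKICPCQWEACGVNFPSFVERNMHNVGQWDMQDKITATEKYTNSEKLYLMDGTVMWEDGLWFVGPIR
>EN_07
TGEMPGEASWSHAHSMWDLQRSIFWSVFQSVVISLLKVQPTKMGQWPDCCLCPQQHWCFCDFDHFMTTRCAINHVHITLCVAMINEFSTFRELSHVHWNYEDTLSMLKAWAECLDGWAFDNRIWERQFLVNIYELICPCQWEACGVNFPSFFERNMSNVCQWDMQDKITATEKYTNSEKLYLMDGTVMWEDGLWFVGPIR
>EN_08
TGEMPGEAEWSHAHSMWWLQRGIFWSVFQSVVWSNLKVQPTKMGQWPDCCLCPQQHWCFCDFDHFYGERPQINMVHITLCVAMVFEFMYCRELGHVHWQYEDTLSMLKPWAEILDGWLFDNRIMERQFLVNTYEKICPCQWEACGVNFPCFFERNMSNVGQWDMQDSITAHEKYTNSEKLYLMDGTVMWEDGLWFVGPIR
>EN_09
TGEMPGEASWSHAHSLWWLQRSIIWSVFQSVVISLLKVQPTKMGQWPDCCLCPQQHWCFCDFDHFMTERCQINHVHITLCVAMVNEFMYFRELGHVHWQYEDTLSMLGPWAEILDGWAFDNRIWERQFLTNIYEKICPCQWEACGVNFPSFFERNMSNVGQWDMQDKITATEKYTNSEHLYLMDGTVMWEDGLWFVGPIM
>EN_10
TGEMPGEASWSHAHSMWWLQRSIHWSVFQSVVISLLKVNPTKMGQWPDCCLCPQQHWCFCDFDHFMTERCQINHVHITLCCAMVNEIMYFRELGHLHDQYADTLSMLKPWAEILDGWAFDNRIWERQFLVNIYEKECPCQWEACGVNFPSFFHRNMSNVGQWDMQDKITATEKYTNSETLYLMDGTVLWEDGCWFVGPIR
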