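>RLE_01
RTIDRRRVMPSSDMWTFTVKRFRMDDKEHFSDFFWCNADPKQWNMNPSSATYGFQMHHAKRCEQIKICEQILREMIHFVANFSTCKSEGTCFKDFEPTYMPFLYWDAYFFEIHMQANYGDYLGGYEWNQLGHKKWADKQWEIMKHQSEHK
>RLE_02
RTIDRRRVMPSSDMWTFTVKRFFFDDKEHFFDFFWCNADPKQWNMNPSSATYYFQMHHATRSEQIKIYEQILREMIHFFANFSTCKSEGTCFKDFEPTYMPFLRWHAYSFEIHPQANYGDYLLGYEWNQLGHKKWADKQWEWRKFQSEHK
>RLE_03
RTIDRRRVMPSSDMWTFTDKRFRGDDKEHFSDFFWCNADPKQNNQNPSSATYGFQMHIAKRCEQIKICEQILREFIHFGANFSTCKSCGTCFKAFEPTYMPFLYWFAYFFEIHMQANYGDYLGGYEWNQLGNKKWQDKQWEIMKHWSEHK
>RLE_04
RTIDRRRVLPSSDMWTFTVKLFRMDDKEHASDFFWCNADFKQWNMNPSSAYYGFQRHHAKRCEQIKICEQYLREMRHFWANFSTCKSEGTCFVDFEPTYMPFLYWDAYFFEIHMQANYGDYLGGREWNQLGHKKWADKQWEIMKHQSEHK
>RLE_05
RTIDRRRVMPSSDMWTFTTKMFRMDDKEHFSDYFWCNVDPKQWNSNPSSATYGFQMHHAKRCEQIKICEQIIREMIHKVANFSTCKSEGDCFKDFMPPYMPFLYWDAYFFEIHMQANYGDYLGGYEWNQLGHKKWADKQWEIMKTQSEHK
>RLE_06
RTQDRRRVMPSSDMWTFTNKRFRMDDKEHWSDFFWCNADPKQWNMNGSSLTYGFQMHHACRCEWIKICEQILREMIHFVANFSLCKSEGTCFKDFNNTYMPFSYWDGYFFEIHMQANYGDYLGGYEISQLGHKKWADKQWEIMKHQPEHK
>RLE_07
RTIDRRRWMPSSDMWTFTVKRFRMDDKEHFSDFFWCNADPKQWNMNPSSATYGFQMHHYKRCEQIKICEQILREMIHFVANFITKKSEGTCFKDFEPTYMPFLDWDAYFFEIHMQANYGDYLGTYEWNQLGFMKWATIQWEMMKHQSEHK
>RLE_08
RTSDRRRVMPSSDMFTFTVKRFRMDLKEHFSDFFWCNADPKQWNMCPSSATNTFQMHHAKRKEQIKICEQICRKMIHFVANFCTCYSEGTCFKDFEPTYMPFLYWDAYFFEIHMQANYGDYLPGYIWNQLVHKKWADKQWEIMKHTSEHK
>RLE_09
RTIDRRRAMPKSDMWTFTVKRFRMDDKEHFSCFFWCNADPKDRNMNPASATYGFTMHHVKRCEQIKICEQIYREMIHFIANFSICKSEGTCFKDFEPTYMPFLYWDAYFFEDHDQANKGDALGGYEWNQLGHKKWADKQWEIMKHISEHK
>RLE_10
RTIDRRRVMPNSDMWTFTVKRFRMDDKEHFMDFFWCNAWPKQWNMNPSSATYGFQMHHAKRCEPIKICEQILREMIHFVANFDTCKSEGTCFKDFNPTYMPFLYWDAYFFEIHAQANYGDYLGGHEWNQLGHKKWADKQWEIMKHQSEPK
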