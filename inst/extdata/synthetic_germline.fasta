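>V01
TAGAATGTACACGGTAACCGCATGTGTCTATTTAACTAGGGTAAAGTTTGATGCGACTTTACTATTACGAAGAGCAAACTAGTTCCTTCTGTTGCACCGTGGAATTATCAGTCGCCCATGTAATGGAGTATATCTCTCATACCCTGGCGCCGGAGCTGTGGTGCATGCTCGGCTTGATCGTGCATTGTCGGTGGCGTAAGCGGCGCTCCTCTGCAAAGCATGTCAGATGAGTACGTTAGTCATGTAGAGTTACTAGGTCCTCTCACTATGCTTGTACACT
>V02
CGATCTCGCGTAGGGTTAGATGCGCAGCTAGCTCACCCTACACGTTGAGGGAAGCAGCTGCTCAGCCTGTTATGTTAGGGACATGAGGTCGCTCCCCCACTCCGAGACGTGGATGACAGTGTAACGTGTTTTGAAAGTAACTCCTTCCCCTCAAGCATTGTTACCAGTACTATCGAGGTCGGGCCTTCAGGCATACGAGATGTCTGTTCTGATCGTGGATACACGACACAACCCCCTGCCAAGTTAAGTGAAATCTCAGGGCACATACTGCACCTTAATT
>V03
CGGTTTGCTAAAGTATCCCGTGTTTTTGCTTCACTTAGTTCTTCGAGTACCCCCACCTTGGCGGTCAAGACTTCTTCGGACAATCCCTTTACAACGATACCGGATTACACCAACGAATTAATTTGCGTCAAGATTGATTATCCCTTAGAGGGCCAGCCCAGAGTGCGCGGGGGGCATCCTGGGTATAATTGCACATGCGACGGTGTCACACAATGTTGAGAAGGATCGTGAGGAGGATCAGTAATTCACGTGCACTGGACATTGATGTTGCATCTATAAA
>V04
ATGAGGATTCCATCGGTCAACTGAGCATTGTGCTATGCAGACGGGATCAGGTGACGGGCACTCTCAAACCGTTGGGGTTTTTTGCGTACGGTATTTGTCGCAGTTTAAATTAAAGACTGGCCGTGCAGGCCGAGGGGTAGTAAAGGGGCACATCACTTAGGCCTTACACAGCTATGTAGCGAATGGGTTTTTGAGGTTCGCTCCTCGCGCAAAGGCACGGCCAATACGTGCGACCATCCCAGGGAGGCTATCAAGTCTATTTAGAACTTGCTCCACGTTG
>V05
CAGGTTTAGAGCTCTTCGGTGTAGATGTGCACATATCGGTTAAACTGCGGTTCTTGGCGCGATGTAGGATGATCCGCTTTCGGAAATTGATTAGACCTTAGCGGTGTTCCCGTGTAGCGGGAGATGCGGTCGTATCTCATTCCAGCTGGCTCATAATTAATAGACGCCATTTTTTCTTCGTAAACTAGCCTCGATACGTGTACCGAGACTCACAGCAGGGAAGCCTGGTCAGTTTCAGGCCGAAATTTCTAGCAAGAACTGTTCGTGTTGTTGCGTCGGC
>V06
AAGTTGTCAGGGTGAAATCAGGCCCCATGAAGTGTGTATCGGGTCCGGACAATAAAGCTACTATGGTTCGCGTGTGCGCACCCCTTTAACTTTGTATCGTCTGCTCCGGATAGCCTCTGCAGAATTCGCTTCACACCCCGGAGTGGTCCATGTTGGGCAGGTGTGCTGATATATGCGCACTGCCGATACTTGGTCACTACTCCATTGGTCTTTAAATGGTTTCTGTGACATGGACACCGCTCACTGTCATGTTCGTGCTACCCAGTTATGTGCTACGATA
>V07
GCTAGGCAGCGCGCATCCTAGTGCTTTAGCTAAACGCCAAGTTGTTAGAGGCCTGGTCTAGCGCTAAAGTTGCTTGCTACACAGAAAAGTTACTTGCATCGTGAGTGTACAAGGTTCTTTGTAGCAAGTTAATACAAGGATCGTTGGTCCCCACTGTTCGAGTTCAAGCGCCACCAAGTATTCTTCCGCAACGAGAGGTAGCATGATCTCTATGAACTCCTGACAGCGCATCCCCTTGACACTGCTACTCAACCTTTACCTGAGTATGTGTGATAACTCT
>V08
ATGGCCGCTTTACGACCTTTATACCTTAATCAATCTATAATCTACGTAGCTGGAGGAGGACGGAACAGCACACCTAATCACTGTTCATTATGGACAGGGTGACGATACACGAATCTGTACCCTTTAGAGGGTGTAGAGGTACGGGATATCGCATTAAAGGTATATACCTAGGGATCTTCTCCGGTGGTATGCGGTAACGGCTACGCCCCCAAGCGAAAGATTACTACTATCCCCATCTATGAGCCCTATGATTTCTCGTGAACCTAAGTGCAACGCAGAG
>J01
ACTCGATGTTTTGGGAAAGGGACTGGCGTGAACGCACAGCGAGACTCTCC
>J02
TGGTCATTTTTCGGAGCTGGTTATCCACGTATTCTATGGGAATCATGCTA
>J03
GATACAATTTTCGGGGCAGGGTGACACTTTCCCGAAGCGAAGAACTGGTC
>J04
AGGCGGACTTTCGGAGGAGGAGCAATAAGAGGGCTCTGATAATCGAAGAG
>J05
CGCGCTACATTTGGCGTAGGTGAAAGGGGGCGTCACCGCACATCTCCTAT
>J06
AAGCGGTACTTCGGGACAGGCGAGGGACTTAGATGCGACAGATCGGACAT
>C01
GTTTGAGCCATCAGAAGCAGAGTTTCGCAGTCATGCCGGGCACGTCTCGATTAATAACTGGTACCTGTTCTAGTAAGTTG
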