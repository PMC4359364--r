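>cenpc_cupin_1
QMYDSCHMTKHHKIGLQTQFVPFMFTWYALAKRMRQGIWSCVKSPCSDIPDWQMEWKCHV
YIKEHFDPMDMYCEISQWQKHKGEMRKQGKDSFRSALLNN
>cenpc_cupin_2
QDHAVCHMTKHHKIGRQTQFFPFMETWYALAYRMRQGAWSCVKSLCSDIPDWQLEWKCHV
YICEHFLPMDMYCVISMWQKHKGEMRKGGKDSFSSALLNN
>cenpc_cupin_3
QDYAVCHMTKHHKIGRQTQFVPFMETWYALAYRMRQGGWSCVKSPCSDILMWQLEWKCHV
YIVEHFDPMDMYCEISQWQKHKGEMRKQGKDSFRSALSNN
>cenpc_cupin_4
QDYAVCHMTKHHKIYRQWQFVPRMETWYALAYRMRSGIWTCVKSPCSDIPCWHLEWKCHV
YIVEHFDPMDMYCEISGWQKHKGEMRKQGKDSFRSALLNN
>other_cupin_1
QDHAQCIMTMARCIGCQFPFVKHMETYYQLACAGRWNDWSFSASPVSQIPDWQNEMKCFT
VTVEQQTPMDWTCEISTCQLHVKALMWMVNCPEWSTLITH
>other_cupin_2
QDHAQCIMTMARCEGCQFQFVKHMETCYQLACAMRWNDWSFSASPVSQIPDWQNEMKCFT
VTVEQQTPMDDTCTDSTCQLHVWALMWMVNCNEWSTLITH
>other_cupin_3
QDHYQSIMTMCRCIGCQFQFVKHMETWYQLACAMRWNDWSFSASPVSQIPDWQNERKCFT
VTVEQQTPIDDTCGISTCQLHVEALMTMWNGNEWSTLITH
>other_cupin_4
QDHAQCIMTMARCIGCQFQFVKHMETWYQLACAMRWNDFSFSASPVSQIPDWQNEMKCFT
VTVEQQTHMDDTCEISTCQLHVWALMWMVNCMEWSTLITH
>outgroup_cupin_1
QFNATWLDYMKTTGWPLTQFWQGMWTMKQELSRMRAGLWSFSNKHDSDWPWWSMEWKCHA
YLSCQMVPMWIYQECSTWQHKPGETVKNGQCEFSLEPEHR
>outgroup_cupin_2
LFNATHLDYMKTGGDPLTQFWQGMWTMNQEGSRMRAGLWSFSNKHDSDWPWLQMEWKCHA
YLSCQVVPMWCHQECSTWQHKPGETVKNGACNFSSEPEHR
>outgroup_cupin_3
QFNATWLDYMKTGHWPLTQFWQGMWTMNQEGSRTRAGLWSISNKHDADWPWWQMEWKCHA
YLSCQMVPYWCYQECSTWQHKPGETVKNGQCNQSSEPEHR
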