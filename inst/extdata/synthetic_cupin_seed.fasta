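>cupin_seed_1
QDYAVCHMTKHHKIGRQTQFVPFMETWYALAYRMRQGIWSCVKSPCSDIPDWQLEWKCHV
YIVEHFDPMDMYCEISQWQKHKGEMRKQGKDSFRSALLNN
>cupin_seed_2
QDYAVCHMTKHHKIGRQTQFVPFMETWYALAYRMRQGIWSCVKSPCSTIPDWQLEWKCHV
YIVEHFDPMDMYCEIQQWQKHKGEMEDQGKDSFRSALLNN
>cupin_seed_3
QDYATCHMTKHMKIGRPTDFVPFMETWYALAYRMRQGIWKCVKSPCSDIPDWQLEWKCHV
YIVEHFDNMDMYCEISQWQKHKGEMRKQGKDSFRSAVLNN
>cupin_seed_4
QDYAVCHMTQHHHIGRVKQFVPFMETWYALAKRMRQGIWSCVKSPPSDIPDWQLEWVCHV
YIVEQFDPMDMYCEIYQWFKPKGEMDKQSKDSFRSALENN
>cupin_seed_5
QKEAVCHMTKHHKIWRQTQFVPFMETWYALAYRMVQGIWSCVKSPCSDILDWQLEWKCHV
YIVEHFDPMDGYCEISQWQKDKGEMRKQRKDSFRSALLNN
>cupin_seed_6
QDYAVCHMTKHYKIGRQAQFVPFMETWYALAYRMRQGIWSCVKSPCSDWPDWQLEWKCHV
YIWEHFDPMDMYCEISQWQKHKGEMRGQGKDSFRSALLNN
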