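system	code
ICD-9	398.91
ICD-9	402.01
ICD-9	402.11
ICD-9	402.91
ICD-9	404.01
ICD-9	404.03
ICD-9	404.11
ICD-9	404.13
ICD-9	404.91
ICD-9	404.93
ICD-9	428.0
ICD-9	428.1
ICD-9	428.20
ICD-9	428.21
ICD-9	428.22
ICD-9	428.23
ICD-9	428.30
ICD-9	428.31
ICD-9	428.32
ICD-9	428.33
ICD-9	428.40
ICD-9	428.41
ICD-9	428.42
ICD-9	428.43
ICD-9	428.9
ICD-10	I09.81
ICD-10	I11.0
ICD-10	I13.0
ICD-10	I13.2
ICD-10	I50.1
ICD-10	I50.20
ICD-10	I50.21
ICD-10	I50.22
ICD-10	I50.23
ICD-10	I50.30
ICD-10	I50.31
ICD-10	I50.32
ICD-10	I50.33
ICD-10	I50.40
ICD-10	I50.41
ICD-10	I50.42
ICD-10	I50.43
ICD-10	I50.810
ICD-10	I50.811
ICD-10	I50.812
ICD-10	I50.813
ICD-10	I50.814
ICD-10	I50.82
ICD-10	I50.83
ICD-10	I50.84
ICD-10	I50.89
ICD-10	I50.9
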