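medication
Metformin
Glucophage
Glipizide
Glyburide
Glimepiride
Sitagliptin
Linagliptin
Empagliflozin
Dapagliflozin
Canagliflozin
Liraglutide
Semaglutide
Pioglitazone
Insulin
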