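"substrate_id","P6","P5","P4","P3","P2","P1"
"syn00001","Y","M","Y","S","P","R"
"syn00002","Y","S","E","V","P","R"
"syn00003","H","Y","A","K","P","R"
"syn00004","V","H","Y","R","G","R"
"syn00005","Q","M","D","C","P","R"
"syn00006","N","Y","N","V","G","R"
"syn00007","S","A","K","C","G","R"
"syn00008","E","E","Y","G","G","R"
"syn00009","R","M","L","Y","G","R"
"syn00010","S","P","V","Q","G","R"
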