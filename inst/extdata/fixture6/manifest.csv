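"subject_id","path","label"
"s001","s001.csv",1
"s002","s002.csv",1
"s003","s003.csv",1
"s004","s004.csv",-1
"s005","s005.csv",-1
"s006","s006.csv",-1
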