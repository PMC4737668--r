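"subject_id","m01","m02","m03"
"s001",0.329215799491689,0.809416329642017,1
"s002",1,0.945130555691698,0.564520338133547
"s003",0.587775856804811,1,0.94217970358775
"s004",0,0.985971066003026,0
"s005",0.213186149929239,0,0.627639433555566
"s006",0.581410573074601,0.0384514251450183,0.472635720885844
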