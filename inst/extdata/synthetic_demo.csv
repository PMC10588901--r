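animal_id,model,group,age_bracket,sex,burrowing,irwin_score,open_field_distance,fcm,saccharin_pref
a0001,demo,naive,,unknown,1.1626852897837976,-0.6281267558439645,-0.24206631448178084,-0.913578847977252,1.0262431851283282
a0002,demo,naive,,unknown,-0.5859244658930509,1.3232208519328272,-1.4720633184205345,1.2455689119871276,-0.3813091793461818
a0003,demo,naive,,unknown,1.785465003316614,-1.5213505700119891,-0.5961595457656964,0.08785471836070449,1.0994352371417806
a0004,demo,naive,,unknown,-1.332593710485012,-0.43742786885669116,-1.1467001312186016,0.4234818950502446,-0.03091713118164364
a0005,demo,sham,,unknown,-0.446566766553219,0.9705775795433993,-2.4746364330588526,-0.8184830165686655,0.1903394199511917
a0006,demo,sham,,unknown,,0.028222644424774936,,-1.5425678370737756,1.335206534998129
a0007,demo,sham,,unknown,-2.8897176144141192,-0.08578218865275929,-0.21631151403810187,0.5558821457316142,0.7305523345454572
a0008,demo,sham,,unknown,-0.8690183433265546,0.38921440498494153,1.5901457684867044,-0.36902897050655437,0.05620189716411944
a0009,demo,treated,,unknown,-0.4617026831496414,1.7366873677129042,1.556143275651943,0.4526617199638814,1.3293056296853196
a0010,demo,treated,,unknown,-0.5555409101374439,1.3555597733059277,1.1084508934835586,1.5181799162475182,-0.4081199426118929
a0011,demo,treated,,unknown,,2.222229700806146,-1.0973418448847738,2.3818775057561616,-0.8182571066992629
a0012,demo,treated,,unknown,-0.1503822241360628,1.8699068574101918,-1.860605716377549,2.3818614952429336,0.35894566992447674
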