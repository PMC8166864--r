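"sample","date","score_urtica","score_parietaria","score_membranacea"
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.9,0.07,0.03
"Leiden_NL","2019-08-23",0.65,0.245,0.105
"Leiden_NL","2019-08-23",0.65,0.245,0.105
"Leiden_NL","2019-08-23",0.65,0.245,0.105
"Leiden_NL","2019-08-23",0.07,0.9,0.03
"Leiden_NL","2019-08-23",0.07,0.9,0.03
"Leiden_NL","2019-08-23",0.07,0.9,0.03
"Leiden_NL","2019-08-23",0.07,0.9,0.03
"Leiden_NL","2019-08-23",0.245,0.65,0.105
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Leiden_NL","2019-08-23",0.45,0.385,0.165
"Lleida_SP","2019-06-16",0.9,0.07,0.03
"Lleida_SP","2019-06-16",0.9,0.07,0.03
"Lleida_SP","2019-06-16",0.9,0.07,0.03
"Lleida_SP","2019-06-16",0.9,0.07,0.03
"Lleida_SP","2019-06-16",0.9,0.07,0.03
"Lleida_SP","2019-06-16",0.9,0.07,0.03
"Lleida_SP","2019-06-16",0.9,0.07,0.03
"Lleida_SP","2019-06-16",0.9,0.07,0.03
"Lleida_SP","2019-06-16",0.65,0.245,0.105
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.07,0.9,0.03
"Lleida_SP","2019-06-16",0.245,0.65,0.105
"Lleida_SP","2019-06-16",0.45,0.385,0.165
"Lleida_SP","2019-06-16",0.45,0.385,0.165
"Lleida_SP","2019-06-16",0.45,0.385,0.165
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.9,0.07,0.03
"Vielha_SP","2019-08-09",0.07,0.9,0.03
"Vielha_SP","2019-08-09",0.07,0.9,0.03
"Vielha_SP","2019-08-09",0.07,0.9,0.03
"Vielha_SP","2019-08-09",0.245,0.65,0.105
"Vielha_SP","2019-08-09",0.245,0.65,0.105
"Vielha_SP","2019-08-09",0.45,0.385,0.165
"Vielha_SP","2019-08-09",0.45,0.385,0.165
"Vielha_SP","2019-08-09",0.45,0.385,0.165
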