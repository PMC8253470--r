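country,metric,period,value
China,rgr,original,0.236
USA,rgr,original,0.228
India,rgr,original,0.224
Pakistan,rgr,original,0.223
Kenya,rgr,original,0.212
Sweden,rgr,original,0.208
China,dt,original,2.33
India,dt,original,2.362
Pakistan,dt,original,2.397
Kenya,dt,original,2.4
Sweden,dt,original,2.464
USA,dt,original,2.514
USA,rgr,forecast,0.329
China,rgr,forecast,0.275
Pakistan,rgr,forecast,0.269
India,rgr,forecast,0.266
Kenya,rgr,forecast,0.261
Sweden,rgr,forecast,0.254
China,dt,forecast,2.117
Pakistan,dt,forecast,2.125
India,dt,forecast,2.143
Kenya,dt,forecast,2.19
USA,dt,forecast,2.193
Sweden,dt,forecast,2.893
USA,rgr,synthetic,0.271
China,rgr,synthetic,0.255
India,rgr,synthetic,0.251
Pakistan,rgr,synthetic,0.248
Kenya,rgr,synthetic,0.246
Sweden,rgr,synthetic,0.231
China,dt,synthetic,2.179
India,dt,synthetic,2.263
Pakistan,dt,synthetic,2.27
Kenya,dt,synthetic,2.276
Sweden,dt,synthetic,2.297
USA,dt,synthetic,2.386
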