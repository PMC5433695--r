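FID1 IID1 FID2 IID2 Z0 Z1 Z2 PI_HAT
fam000001 1 fam000001 2 0.304773 0.494579 0.200648 0.447937
fam000002 1 fam000002 2 0.200895 0.494636 0.304469 0.551787
fam000003 1 fam000003 2 0.213309 0.497090 0.289601 0.538146
fam000004 1 fam000004 2 0.281494 0.498132 0.220373 0.469439
fam000005 1 fam000005 2 0.255707 0.499936 0.244357 0.494325
fam000006 1 fam000006 2 0.221639 0.498293 0.280068 0.529214
fam000007 1 fam000007 2 0.198456 0.494056 0.307488 0.554516
fam000008 1 fam000008 2 0.252149 0.499991 0.247860 0.497856
fam000009 1 fam000009 2 0.328191 0.489377 0.182432 0.427121
fam000010 1 fam000010 2 0.229461 0.499120 0.271420 0.520979
fam000011 1 fam000011 2 0.271638 0.499102 0.229260 0.478811
fam000012 1 fam000012 2 0.246374 0.499974 0.253652 0.503639
fam000013 1 fam000013 2 0.286961 0.497453 0.215587 0.464313
fam000014 1 fam000014 2 0.294990 0.496280 0.208730 0.456870
fam000015 1 fam000015 2 0.220343 0.498128 0.281529 0.530593
fam000016 1 fam000016 2 0.225241 0.498709 0.276050 0.525405
fam000017 1 fam000017 2 0.280509 0.498244 0.221247 0.470369
fam000018 1 fam000018 2 0.270598 0.499185 0.230217 0.479809
fam000019 1 fam000019 2 0.227593 0.498948 0.273459 0.522933
fam000020 1 fam000020 2 0.364153 0.478596 0.157251 0.396549
fam000021 1 fam000021 2 0.276096 0.498705 0.225199 0.474552
fam000022 1 fam000022 2 0.205244 0.495589 0.299166 0.546961
fam000023 1 fam000023 2 0.243454 0.499913 0.256632 0.506589
fam000024 1 fam000024 2 0.268841 0.499316 0.231843 0.481501
fam000025 1 fam000025 2 0.223135 0.498473 0.278392 0.527628
fam000026 1 fam000026 2 0.283378 0.497909 0.218712 0.467667
fam000027 1 fam000027 2 0.257629 0.499885 0.242486 0.492428
fam000028 1 fam000028 2 0.227227 0.498913 0.273860 0.523317
fam000029 1 fam000029 2 0.269256 0.499286 0.231458 0.481101
fam000030 1 fam000030 2 0.263496 0.499645 0.236859 0.486681
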