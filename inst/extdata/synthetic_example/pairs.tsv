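pair_id	pheno_proband	pheno_sib	pi_hat	snp1_p	snp2_p	snp3_p	snp1_s	snp2_s	snp3_s	dr34_proband	dr34_sib
fam000001:1:fam000001:2	1	0	0.447937	1	1	1	0	1	0	1	0
fam000002:1:fam000002:2	1	0	0.551787	1	0	1	1	0	0	1	0
fam000003:1:fam000003:2	1	0	0.538146	1	1	1	1	1	0	1	0
fam000004:1:fam000004:2	1	0	0.469439	1	1	2	2	1	1	0	1
fam000005:1:fam000005:2	1	0	0.494325	2	2	0	1	1	0	0	0
fam000006:1:fam000006:2	1	0	0.529214	1	1	1	2	0	1	1	0
fam000007:1:fam000007:2	1	0	0.554516	0	1	0	1	1	0	1	1
fam000008:1:fam000008:2	1	0	0.497856	2	1	1	2	1	1	1	1
fam000009:1:fam000009:2	1	0	0.427121	0	2	1	0	2	1	1	1
fam000010:1:fam000010:2	1	0	0.520979	1	1	1	1	0	1	1	0
fam000011:1:fam000011:2	1	0	0.478811	0	1	0	0	0	0	0	0
fam000012:1:fam000012:2	1	0	0.503639	0	2	1	2	2	0	1	0
fam000013:1:fam000013:2	1	0	0.464313	0	0	1	1	0	1	1	0
fam000014:1:fam000014:2	1	0	0.456870	1	0	0	0	0	0	0	0
fam000015:1:fam000015:2	1	0	0.530593	0	2	0	0	2	1	0	1
fam000016:1:fam000016:2	1	1	0.525405	1	1	1	1	0	1	1	0
fam000017:1:fam000017:2	1	0	0.470369	0	1	1	0	2	0	1	0
fam000018:1:fam000018:2	1	0	0.479809	0	0	0	0	1	0	0	0
fam000019:1:fam000019:2	1	0	0.522933	1	1	0	2	2	0	0	0
fam000020:1:fam000020:2	1	0	0.396549	2	1	1	0	2	2	0	0
fam000021:1:fam000021:2	1	0	0.474552	1	1	2	0	1	1	1	1
fam000022:1:fam000022:2	1	0	0.546961	0	2	2	0	1	1	0	1
fam000023:1:fam000023:2	1	0	0.506589	0	1	1	2	1	2	1	1
fam000024:1:fam000024:2	1	0	0.481501	1	1	2	1	1	1	1	1
fam000025:1:fam000025:2	1	0	0.527628	0	1	1	0	1	1	1	0
fam000026:1:fam000026:2	1	0	0.467667	0	1	0	1	1	0	0	0
fam000027:1:fam000027:2	1	1	0.492428	2	2	2	2	1	1	1	1
fam000028:1:fam000028:2	1	0	0.523317	0	0	1	0	0	1	0	0
fam000029:1:fam000029:2	1	0	0.481101	1	1	0	1	1	0	0	0
fam000030:1:fam000030:2	1	0	0.486681	1	1	0	0	1	1	0	1
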