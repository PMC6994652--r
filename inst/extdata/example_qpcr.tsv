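sample_id	gene_id	ct_target	ct_reference	group	replicate
het1	RS_g0012	24.1	20.2	heterograft	1
het2	RS_g0012	24.3	20.1	heterograft	2
pos1	RS_g0012	21.9	20.3	positive-control	1
pos2	RS_g0012	22.1	20.2	positive-control	2
neg1	RS_g0012		20.4	negative-control	1
neg2	RS_g0012		20.2	negative-control	2
het1	RS_g0077	27.6	20.2	heterograft	1
het2	RS_g0077	27.8	20.1	heterograft	2
pos1	RS_g0077	24.0	20.3	positive-control	1
pos2	RS_g0077	24.2	20.2	positive-control	2
neg1	RS_g0077	27.5	20.4	negative-control	1
neg2	RS_g0077	27.7	20.2	negative-control	2
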