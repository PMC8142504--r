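checkpoint	immune checkpoint signature	CD274	CTLA4	HAVCR2	LAG3	PDCD1	PDCD1LG2
INFG	interferon gamma signature	CXCL10	CXCL9	HLA-DRA	IDO1	IFNG	STAT1
CD8	CD8 signature	CD8A	CD8B
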