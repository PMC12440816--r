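# synthetic example qPCR table (three technical replicates per cell)
region	condition	ct
re_replication	galactose	19.1
re_replication	galactose	19.0
re_replication	galactose	19.2
re_replication	glucose	21.0
re_replication	glucose	21.1
re_replication	glucose	20.9
internal_control	galactose	20.0
internal_control	galactose	20.1
internal_control	galactose	19.9
internal_control	glucose	20.0
internal_control	glucose	20.1
internal_control	glucose	19.9
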