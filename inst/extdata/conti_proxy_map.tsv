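source_id	proxy_id	r2	same_direction	rule
rsC00042	rsPAIR001,rsPAIR002	1	TRUE	two_marker
rsC00007	rsC00007_tag	0.91	TRUE	single
rsC00019	rsC00019_tag	0.55	FALSE	single
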