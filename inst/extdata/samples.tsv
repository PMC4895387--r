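sample_id	condition
s1	case
s2	case
s3	control
s4	control
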