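subject_id	group	age	sex	cohort_tag
sub01	control	44.5	male	c1
sub02	exposed	51.2	male	nfl
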