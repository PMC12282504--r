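group,hispanic,non_hispanic
ED,9,82
HC,7,41
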