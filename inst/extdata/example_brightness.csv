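"fluorophore","brightness"
"mAzure",32.5
"mJade",54
"mGarnet",21
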