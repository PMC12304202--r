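phase,pnd,n_calls
DEV6,6,60305
DEV9,9,69055
DEV12,12,82836
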