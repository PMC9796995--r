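participant_id,age,education,mmse
example,74,12,19
example-list,71,10,22
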