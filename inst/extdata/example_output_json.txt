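{ annotations:[ {entity: sub-Saharan origin, category: not applicable}, {entity:sweating and fever} ]
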