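node,score,description
A1,4,Policy enforcement is strong and law enforcement standardization is high
A2,3,Implementation of the main responsibility is not sufficient
A3,3.5,Detection mechanism is well-developed but coverage is insufficient
A4,3.5,Public enthusiasm for supervision needs to be enhanced
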