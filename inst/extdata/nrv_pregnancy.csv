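nutrient,kind,threshold
protein,EAR,49
fiber,AI,28
iron,EAR,22
zinc,EAR,9.0
calcium,EAR,840
folate,EAR,520
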