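node_id,label
n1,visual
n2,visual
n3,visual
n4,visual
n5,visual
n6,visual
n7,visual
n8,visual
n9,somatomotor
n10,somatomotor
n11,somatomotor
n12,somatomotor
n13,somatomotor
n14,somatomotor
n15,somatomotor
n16,somatomotor
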