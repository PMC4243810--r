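(lamprey:5.0,((zebrafish:3.2,(medaka:1.8,tetraodon:1.8)acanthomorph_ancestor:1.4)teleost_ancestor:1.4,(coelacanth:4.2,(xenopus:3.6,(((human:1.0,(mouse:0.6,rat:0.6)murine_ancestor:0.4)eutherian_ancestor:0.8,opossum:1.8)mammal_ancestor:1.2,((chicken:1.0,duck:1.0)bird_ancestor:1.2,(alligator:1.6,turtle:1.6)archosauromorph_ancestor:0.6)sauropsid_ancestor:0.8)amniote_ancestor:0.6)tetrapod_ancestor:0.6)sarcopterygian_ancestor:0.4)osteichthyan_ancestor:0.4)vertebrate_ancestor;
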