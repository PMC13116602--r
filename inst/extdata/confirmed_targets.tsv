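serpin_name	confirmed_targets
S12c5	chymotrypsin; human chymase; cathepsin G
S13c5	trypsin IV; trypsin; factor Xa; factor XIa; factor IXa; plasmin; chymase; cathepsin G
S41c10	trypsin IV; trypsin; thrombin; human chymase; alpha-chymotrypsin; cathepsin G
S45c10	porcine elastase; chymotrypsin; human chymase; cathepsin G
S48c10	kallikrein; chymotrypsin; human chymase; cathepsin G
S49c10	trypsin IV; trypsin; human chymase; cathepsin G
S51c10	trypsin; thrombin; cathepsin G; factor Xa
S61c10	trypsin IV; trypsin; factor Xa; factor XIa; plasmin; cathepsin G
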