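alert_id,smarts,description
thioether,[#16X2](-[#6])-[#6],dialkyl/aryl thioether (aromatic sulfur excluded)
sulfoxide,[#16X3](=[OX1])(-[#6])-[#6],sulfoxide
hydrazine,[NX3;!a]-[NX3;!a],hydrazine / hydrazide N-N
azide,N=[N+]=[N-],azide
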