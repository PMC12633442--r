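"area_a","area_b","outcome_label","provenance"
"8","9","RTP","area-by-area account"
"8","46","RTP","area-by-area account"
"8","9/46","RTP","area-by-area account"
"8","44","RTP","area-by-area account"
"8","45","TP","area-by-area account"
"8","47","TP","area-by-area account"
"8","10","TP","area-by-area account"
"8","11","TN","area-by-area account"
"8","13","FN","area-by-area account"
"8","14","FN","area-by-area account"
"8","24","TP","area-by-area account"
"8","25","TN","area-by-area account"
"8","32","RTP","area-by-area account"
"9","46","RTP","area-by-area account"
"9","9/46","RTP","area-by-area account"
"9","44","RTP","area account gives TP; RTP reconciles the overall robust-true-positive total (41)"
"9","45","RTP","area-by-area account"
"9","47","RTP","area-by-area account"
"9","10","RTP","area-by-area account"
"9","11","FP","area-by-area account"
"9","13","FP","area-by-area account"
"9","14","FP","conflicting area accounts (FN vs FP); FP follows partition summary tallies"
"9","24","RTP","area-by-area account"
"9","25","TN","area-by-area account"
"9","32","RTP","area-by-area account"
"46","9/46","RTP","area-by-area account"
"46","44","RTP","area-by-area account"
"46","45","TP","area-by-area account"
"46","47","RTP","area-by-area account"
"46","10","TP","area-by-area account"
"46","11","TN","area-by-area account"
"46","13","TN","area-by-area account"
"46","14","TN","area-by-area account"
"46","24","FN","area-by-area account"
"46","25","TN","area-by-area account"
"46","32","FP","area-by-area account"
"9/46","44","RTP","area-by-area account"
"9/46","45","RTP","area-by-area account"
"9/46","47","RTP","area-by-area account"
"9/46","10","RTP","area-by-area account"
"9/46","11","FP","conflicting area accounts (FN vs FP); FP follows partition summary tallies"
"9/46","13","FN","area-by-area account"
"9/46","14","FN","area-by-area account"
"9/46","24","FN","area-by-area account"
"9/46","25","TN","area-by-area account"
"9/46","32","FP","conflicting area accounts (FN vs FP); FP follows partition summary tallies"
"44","45","RTP","area-by-area account"
"44","47","RTP","area-by-area account"
"44","10","TN","area-by-area account"
"44","11","TN","area-by-area account"
"44","13","TN","area-by-area account"
"44","14","TN","area-by-area account"
"44","24","FP","area-by-area account"
"44","25","TN","area-by-area account"
"44","32","FP","area-by-area account"
"45","47","RTP","area-by-area account"
"45","10","TP","area-by-area account"
"45","11","FP","area-by-area account"
"45","13","FN","area-by-area account"
"45","14","TN","area-by-area account"
"45","24","FN","area-by-area account"
"45","25","FP","area account gives TN; FP reconciles the ventrolateral partition tallies (20/7/6/3)"
"45","32","FP","area-by-area account"
"47","10","RTP","area-by-area account"
"47","11","RTP","area-by-area account"
"47","13","RTP","area-by-area account"
"47","14","RTP","area-by-area account"
"47","24","FN","area-by-area account"
"47","25","TN","area-by-area account"
"47","32","FP","area-by-area account"
"10","11","RTP","area-by-area account"
"10","13","RTP","area-by-area account"
"10","14","RTP","area-by-area account"
"10","24","RTP","conflicting area accounts (RTP vs TP); RTP follows frontal-pole summary counts"
"10","25","RTP","area-by-area account"
"10","32","RTP","area-by-area account"
"11","13","RTP","area-by-area account"
"11","14","RTP","area-by-area account"
"11","24","FN","area-by-area account"
"11","25","TN","area-by-area account"
"11","32","TN","area account gives FP; TN reconciles the orbitofrontal partition agreement (22/36)"
"13","14","RTP","area-by-area account"
"13","24","FN","area-by-area account"
"13","25","FN","area-by-area account"
"13","32","FP","area-by-area account"
"14","24","TP","area-by-area account"
"14","25","RTP","area-by-area account"
"14","32","RTP","area-by-area account"
"24","25","RTP","area-by-area account"
"24","32","RTP","area-by-area account"
"25","32","RTP","area-by-area account"
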