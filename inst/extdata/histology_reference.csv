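"area_a","area_b","histology_status","provenance"
"8","9","present","consistent precedence across primate tract-tracing reports"
"8","46","present","consistent precedence across primate tract-tracing reports"
"8","9/46","present","consistent precedence across primate tract-tracing reports"
"8","44","present","consistent precedence across primate tract-tracing reports"
"8","45","present","consistent precedence across primate tract-tracing reports"
"8","47","present","consistent precedence across primate tract-tracing reports"
"8","10","present","consistent precedence across primate tract-tracing reports"
"8","11","absent","no consistent histological precedence"
"8","13","present","consistent precedence across primate tract-tracing reports"
"8","14","present","consistent precedence across primate tract-tracing reports"
"8","24","present","consistent precedence across primate tract-tracing reports"
"8","25","absent","no consistent histological precedence"
"8","32","present","consistent precedence across primate tract-tracing reports"
"9","46","present","consistent precedence across primate tract-tracing reports"
"9","9/46","present","consistent precedence across primate tract-tracing reports"
"9","44","present","consistent precedence across primate tract-tracing reports"
"9","45","present","consistent precedence across primate tract-tracing reports"
"9","47","present","consistent precedence across primate tract-tracing reports"
"9","10","present","consistent precedence across primate tract-tracing reports"
"9","11","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"9","13","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"9","14","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"9","24","present","consistent precedence across primate tract-tracing reports"
"9","25","absent","no consistent histological precedence"
"9","32","present","consistent precedence across primate tract-tracing reports"
"46","9/46","present","consistent precedence across primate tract-tracing reports"
"46","44","present","consistent precedence across primate tract-tracing reports"
"46","45","present","consistent precedence across primate tract-tracing reports"
"46","47","present","consistent precedence across primate tract-tracing reports"
"46","10","present","consistent precedence across primate tract-tracing reports"
"46","11","absent","no consistent histological precedence"
"46","13","absent","no consistent histological precedence"
"46","14","absent","no consistent histological precedence"
"46","24","present","consistent precedence across primate tract-tracing reports"
"46","25","absent","no consistent histological precedence"
"46","32","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"9/46","44","present","consistent precedence across primate tract-tracing reports"
"9/46","45","present","consistent precedence across primate tract-tracing reports"
"9/46","47","present","consistent precedence across primate tract-tracing reports"
"9/46","10","present","consistent precedence across primate tract-tracing reports"
"9/46","11","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"9/46","13","present","consistent precedence across primate tract-tracing reports"
"9/46","14","present","consistent precedence across primate tract-tracing reports"
"9/46","24","present","consistent precedence across primate tract-tracing reports"
"9/46","25","absent","no consistent histological precedence"
"9/46","32","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"44","45","present","consistent precedence across primate tract-tracing reports"
"44","47","present","consistent precedence across primate tract-tracing reports"
"44","10","absent","no consistent histological precedence"
"44","11","absent","no consistent histological precedence"
"44","13","absent","no consistent histological precedence"
"44","14","absent","no consistent histological precedence"
"44","24","absent","no consistent histological precedence"
"44","25","absent","no consistent histological precedence"
"44","32","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"45","47","present","consistent precedence across primate tract-tracing reports"
"45","10","present","consistent precedence across primate tract-tracing reports"
"45","11","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"45","13","present","consistent precedence across primate tract-tracing reports"
"45","14","absent","no consistent histological precedence"
"45","24","present","consistent precedence across primate tract-tracing reports"
"45","25","absent","no consistent histological precedence"
"45","32","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"47","10","present","consistent precedence across primate tract-tracing reports"
"47","11","present","consistent precedence across primate tract-tracing reports"
"47","13","present","consistent precedence across primate tract-tracing reports"
"47","14","present","consistent precedence across primate tract-tracing reports"
"47","24","present","consistent precedence across primate tract-tracing reports"
"47","25","absent","no consistent histological precedence"
"47","32","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"10","11","present","consistent precedence across primate tract-tracing reports"
"10","13","present","consistent precedence across primate tract-tracing reports"
"10","14","present","consistent precedence across primate tract-tracing reports"
"10","24","present","consistent precedence across primate tract-tracing reports"
"10","25","present","consistent precedence across primate tract-tracing reports"
"10","32","present","consistent precedence across primate tract-tracing reports"
"11","13","present","consistent precedence across primate tract-tracing reports"
"11","14","present","consistent precedence across primate tract-tracing reports"
"11","24","present","consistent precedence across primate tract-tracing reports"
"11","25","absent","no consistent histological precedence"
"11","32","absent","no consistent histological precedence"
"13","14","present","consistent precedence across primate tract-tracing reports"
"13","24","present","consistent precedence across primate tract-tracing reports"
"13","25","present","consistent precedence across primate tract-tracing reports"
"13","32","present","histological precedence; reconstructed trajectory anatomically implausible (trajectory FP)"
"14","24","present","consistent precedence across primate tract-tracing reports"
"14","25","present","consistent precedence across primate tract-tracing reports"
"14","32","present","consistent precedence across primate tract-tracing reports"
"24","25","present","consistent precedence across primate tract-tracing reports"
"24","32","present","consistent precedence across primate tract-tracing reports"
"25","32","present","consistent precedence across primate tract-tracing reports"
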