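"area_id","partition","description"
"8","dlPFC","dorsal and posterior superior frontal gyrus, reaching the middle frontal gyrus and medial wall"
"9","dlPFC","rostral superior frontal gyrus, bounded by the superior frontal sulcus"
"46","dlPFC","central middle frontal gyrus, bounded anteriorly and posteriorly by area 9/46"
"9/46","dlPFC","middle frontal gyrus, surrounding area 46 (dorsal and ventral portions)"
"44","vlPFC","pars opercularis of the inferior frontal gyrus (Broca's area)"
"45","vlPFC","pars triangularis of the inferior frontal gyrus"
"47","vlPFC","pars orbitalis of the inferior frontal gyrus and lateral orbital gyri"
"10","FrontalPole","frontal pole, most anterior portion of the prefrontal cortex"
"11","OFC","anterior orbital gyri"
"13","OFC","posterior-lateral orbital surface"
"14","OFC","posterior-medial orbital surface"
"24","ACC","cingulate gyrus bounding the genu of the corpus callosum"
"25","ACC","subgenual cingulate, ventral to the genu of the corpus callosum"
"32","ACC","anterior cingulate, anterodorsal to area 24"
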