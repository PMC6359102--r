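{"session":"synthetic_stroop","seed":42,"duration":16,"track":[{"difficulty":1,"congruency":"congruent","start":0,"end":2,"raw_label":1,"label":0},{"difficulty":1,"congruency":"incongruent","start":2,"end":4,"raw_label":5,"label":0.571428571428571},{"difficulty":2,"congruency":"congruent","start":4,"end":6,"raw_label":2,"label":0.142857142857143},{"difficulty":2,"congruency":"incongruent","start":6,"end":8,"raw_label":6,"label":0.714285714285714},{"difficulty":3,"congruency":"congruent","start":8,"end":10,"raw_label":3,"label":0.285714285714286},{"difficulty":3,"congruency":"incongruent","start":10,"end":12,"raw_label":7,"label":0.857142857142857},{"difficulty":4,"congruency":"congruent","start":12,"end":14,"raw_label":4,"label":0.428571428571429},{"difficulty":4,"congruency":"incongruent","start":14,"end":16,"raw_label":8,"label":1}]}
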