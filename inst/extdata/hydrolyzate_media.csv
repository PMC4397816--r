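medium_id,glucose,xylose,arabinose,galactose,mannose,fructose,acetic_acid,hmf,furfural,pan,urea,ammonia
AFEX-CSH-6,58.9,34.2,4.3,3.1,1.0,4.0,1.8,0.3,0.2,318.7,83.1,1193.4
AFEX-CSH-12,107.4,48.7,9.5,5.7,2.0,8.2,4.7,1.1,0.4,493.2,105.5,2707.6
PSGHL,7.9,52.1,7.6,3.0,8.9,0.9,6.1,2.8,24.4,33.7,0.7,25.0
SGH,69.2,48.6,6.1,5.2,0,0.7,5.4,1.8,18.3,69.9,7.0,23.0
SGH-N1,67.4,45.3,4.4,5.2,0,0.7,4.3,1.1,24.5,188.0,110,369.0
SGH-N2,64.2,47.4,7.6,5.2,0,0.7,5.8,3.6,19.1,173.0,962.0,
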