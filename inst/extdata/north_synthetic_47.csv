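longitude,latitude,population
-73.058519,-37.633216,north
-72.970894,-37.719,north
-72.815437,-37.592469,north
-72.81982,-37.637844,north
-72.816888,-37.729587,north
-72.889191,-37.696859,north
-72.974929,-37.762844,north
-73.091288,-37.7015,north
-72.822564,-37.757373,north
-73.028384,-37.854424,north
-73.110835,-37.763411,north
-72.985583,-37.607192,north
-72.947348,-37.816729,north
-72.97807,-37.900792,north
-72.890578,-37.654933,north
-73.051164,-37.688212,north
-72.861805,-37.648994,north
-72.905883,-37.641943,north
-73.193549,-37.826657,north
-72.853373,-37.851702,north
-73.134657,-37.639572,north
-73.052658,-37.759319,north
-73.143186,-37.692927,north
-73.029613,-37.700788,north
-72.929618,-37.689743,north
-73.092295,-37.906455,north
-73.072148,-37.597163,north
-73.05414,-37.884975,north
-73.199025,-37.727436,north
-73.098573,-37.740068,north
-73.134999,-37.886022,north
-72.896327,-37.600908,north
-72.842263,-37.764515,north
-73.158908,-37.681108,north
-73.135431,-37.734891,north
-73.09083,-37.59883,north
-73.180006,-37.721923,north
-73.181086,-37.772212,north
-73.1345,-37.819648,north
-73.189453,-37.688506,north
-73.095882,-37.602371,north
-73.191197,-37.633617,north
-73.146175,-37.847436,north
-73.092915,-37.814684,north
-72.895987,-37.821321,north
-72.969532,-37.634513,north
-73.050695,-37.701871,north
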