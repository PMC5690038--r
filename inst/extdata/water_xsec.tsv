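# Water photon mass interaction coefficients (cm^2/g), 0.01-1.40 MeV.
# Constructed from closed forms (see build_water_xsec in the gkmc package):
#   mu_compton : analytic Klein-Nishina cross section x 3.342804e23 e/g
#                (free-electron approximation; agrees with standard water
#                incoherent data to ~1% at 1.25 MeV, ~3% at 50 keV)
#   mu_photo   : parametric 0.0100*(0.05/E)^3 anchored at 50 keV
#   mu_pair    : parametric quadratic above the 1.022 MeV threshold
#   mu_en      : Klein-Nishina energy-transfer integral + photo + pair
# Coherent (Rayleigh) scattering is neglected (no energy transfer).
# Regenerated by build_water_xsec(); a unit test enforces equality.
energy	mu_compton	mu_photo	mu_pair	mu_total	mu_en
1.000000000e-02	2.140966569e-01	1.250000000e+00	0.000000000e+00	1.464096657e+00	1.254017230e+00
1.072079904e-02	2.135306139e-01	1.014445095e+00	0.000000000e+00	1.227975709e+00	1.018727822e+00
1.149355321e-02	2.129281363e-01	8.232790810e-01	0.000000000e+00	1.036207217e+00	8.278431148e-01
1.232200743e-02	2.122871943e-01	6.681371406e-01	0.000000000e+00	8.804243349e-01	6.729989927e-01
1.321017655e-02	2.116056895e-01	5.422307562e-01	0.000000000e+00	7.538364457e-01	5.474076353e-01
1.416236481e-02	2.108814582e-01	4.400506649e-01	0.000000000e+00	6.509321231e-01	4.455604683e-01
1.518318671e-02	2.101122774e-01	3.571257909e-01	0.000000000e+00	5.672380683e-01	3.629870894e-01
1.627758935e-02	2.092958707e-01	2.898276056e-01	0.000000000e+00	4.991234763e-01	2.960596201e-01
1.745087644e-02	2.084299168e-01	2.352113544e-01	0.000000000e+00	4.436412711e-01	2.418339256e-01
1.870873394e-02	2.075120586e-01	1.908872038e-01	0.000000000e+00	3.983992625e-01	1.979207512e-01
2.005725769e-02	2.065399150e-01	1.549156701e-01	0.000000000e+00	3.614555852e-01	1.623811419e-01
2.150298291e-02	2.055110932e-01	1.257227534e-01	0.000000000e+00	3.312338466e-01	1.336415652e-01
2.305291586e-02	2.044232038e-01	1.020310644e-01	0.000000000e+00	3.064542683e-01	1.104250261e-01
2.471456783e-02	2.032738780e-01	8.280393031e-02	0.000000000e+00	2.860778083e-01	9.169516056e-02
2.649599152e-02	2.020607859e-01	6.720003277e-02	0.000000000e+00	2.692608187e-01	7.661086028e-02
2.840582005e-02	2.007816573e-01	5.453659492e-02	0.000000000e+00	2.553182523e-01	6.448944608e-02
3.045330884e-02	1.994343052e-01	4.425950498e-02	0.000000000e+00	2.436938102e-01	5.477677766e-02
3.264838043e-02	1.980166497e-01	3.591907020e-02	0.000000000e+00	2.339357199e-01	4.702299336e-02
3.500167257e-02	1.965267453e-01	2.915033967e-02	0.000000000e+00	2.256770850e-01	4.086281930e-02
3.752458978e-02	1.949628086e-01	2.365713528e-02	0.000000000e+00	2.186199439e-01	3.599958685e-02
4.022935862e-02	1.933232482e-01	1.919909188e-02	0.000000000e+00	2.125223401e-01	3.219226044e-02
4.312908694e-02	1.916066948e-01	1.558113968e-02	0.000000000e+00	2.071878345e-01	2.924490874e-02
4.623782740e-02	1.898120330e-01	1.264496858e-02	0.000000000e+00	2.024570016e-01	2.699815948e-02
4.957064558e-02	1.879384317e-01	1.026210108e-02	0.000000000e+00	1.982005328e-01	2.532226508e-02
5.314369297e-02	1.859853755e-01	8.328270488e-03	0.000000000e+00	1.943136459e-01	2.411147609e-02
5.697428528e-02	1.839526935e-01	6.758858519e-03	0.000000000e+00	1.907115520e-01	2.327947718e-02
6.108098631e-02	1.818405875e-01	5.485192699e-03	0.000000000e+00	1.873257802e-01	2.275568640e-02
6.548369796e-02	1.796496562e-01	4.451541464e-03	0.000000000e+00	1.841011977e-01	2.248225592e-02
7.020375664e-02	1.773809167e-01	3.612675524e-03	0.000000000e+00	1.809935922e-01	2.241164328e-02
7.526403671e-02	1.750358210e-01	2.931888773e-03	0.000000000e+00	1.779677098e-01	2.250464634e-02
8.068906127e-02	1.726162677e-01	2.379392148e-03	0.000000000e+00	1.749956598e-01	2.272881574e-02
8.650512109e-02	1.701246070e-01	1.931010156e-03	0.000000000e+00	1.720556172e-01	2.305717407e-02
9.274040194e-02	1.675636398e-01	1.567123025e-03	0.000000000e+00	1.691307628e-01	2.346718480e-02
9.942512124e-02	1.649366085e-01	1.271808213e-03	0.000000000e+00	1.662084167e-01	2.393992398e-02
1.065916745e-01	1.622471806e-01	1.032143683e-03	0.000000000e+00	1.632793243e-01	2.445941668e-02
1.142747922e-01	1.594994247e-01	8.376424775e-04	0.000000000e+00	1.603370671e-01	2.501210676e-02
1.225117083e-01	1.566977774e-01	6.797938423e-04	0.000000000e+00	1.573775713e-01	2.558643431e-02
1.313423405e-01	1.538470045e-01	5.516908233e-04	0.000000000e+00	1.543986953e-01	2.617249970e-02
1.408094838e-01	1.509521532e-01	4.477280398e-04	0.000000000e+00	1.513998812e-01	2.676179668e-02
1.509590179e-01	1.480184999e-01	3.633564112e-04	0.000000000e+00	1.483818563e-01	2.734700026e-02
1.618401295e-01	1.450514919e-01	2.948841033e-04	0.000000000e+00	1.453463761e-01	2.792179755e-02
1.735055506e-01	1.420566862e-01	2.393149858e-04	0.000000000e+00	1.422960012e-01	2.848075184e-02
1.860118140e-01	1.390396855e-01	1.942175309e-04	0.000000000e+00	1.392339030e-01	2.901919207e-02
1.994195278e-01	1.360060750e-01	1.576184173e-04	0.000000000e+00	1.361636934e-01	2.953312142e-02
2.137936683e-01	1.329613594e-01	1.279161843e-04	0.000000000e+00	1.330892756e-01	3.001914005e-02
2.292038955e-01	1.299109038e-01	1.038111566e-04	0.000000000e+00	1.300147150e-01	3.047437822e-02
2.457248903e-01	1.268598791e-01	8.424857491e-05	0.000000000e+00	1.269441277e-01	3.089643709e-02
2.634367169e-01	1.238132138e-01	6.837244288e-05	0.000000000e+00	1.238815863e-01	3.128333516e-02
2.824252103e-01	1.207755532e-01	5.548807146e-05	0.000000000e+00	1.208310413e-01	3.163345932e-02
3.027823924e-01	1.177512269e-01	4.503168155e-05	0.000000000e+00	1.177962586e-01	3.194551981e-02
3.246069183e-01	1.147442259e-01	3.654573479e-05	0.000000000e+00	1.147807717e-01	3.221850891e-02
3.480045539e-01	1.117581882e-01	2.965891312e-05	0.000000000e+00	1.117878471e-01	3.245166347e-02
3.730886888e-01	1.087963938e-01	2.406987116e-05	0.000000000e+00	1.088204636e-01	3.264443144e-02
3.999808858e-01	1.058617688e-01	1.953405019e-05	0.000000000e+00	1.058813029e-01	3.279644294e-02
4.288114698e-01	1.029568969e-01	1.585297713e-05	0.000000000e+00	1.029727498e-01	3.290748586e-02
4.597201596e-01	1.000840374e-01	1.286557991e-05	0.000000000e+00	1.000969030e-01	3.297748630e-02
4.928567447e-01	9.724514983e-02	1.044113955e-05	0.000000000e+00	9.725559096e-02	3.300649391e-02
5.283818117e-01	9.444192181e-02	8.473570246e-06	0.000000000e+00	9.445039538e-02	3.299467165e-02
5.664675221e-01	9.167580027e-02	6.876777420e-06	0.000000000e+00	9.168267705e-02	3.294228995e-02
6.072984469e-01	8.894802397e-02	5.580890500e-06	0.000000000e+00	8.895360486e-02	3.284972440e-02
6.510724609e-01	8.625965619e-02	4.529205596e-06	0.000000000e+00	8.626418540e-02	3.271745646e-02
6.980017016e-01	8.361161637e-02	3.675704322e-06	0.000000000e+00	8.361529207e-02	3.254607636e-02
7.483135975e-01	8.100470972e-02	2.983040177e-06	0.000000000e+00	8.100769276e-02	3.233628726e-02
8.022519700e-01	7.843965399e-02	2.420904381e-06	0.000000000e+00	7.844207489e-02	3.208891000e-02
8.600782153e-01	7.591710275e-02	1.964699660e-06	0.000000000e+00	7.591906745e-02	3.180488758e-02
9.220725707e-01	7.343766496e-02	1.594463947e-06	0.000000000e+00	7.343925942e-02	3.148528863e-02
9.885354734e-01	7.100192035e-02	1.293996905e-06	0.000000000e+00	7.100321435e-02	3.113130935e-02
1.059789016e+00	6.861043098e-02	1.050151051e-06	3.010987854e-07	6.861178223e-02	3.074428430e-02
1.136178507e+00	6.626374880e-02	8.522564660e-07	2.748612960e-06	6.626734967e-02	3.032590664e-02
1.218074145e+00	6.396241971e-02	6.916539135e-07	8.105479637e-06	6.397121685e-02	2.987825449e-02
1.305872813e+00	6.170698445e-02	5.613159361e-07	1.698958319e-05	6.172453535e-02	2.940360820e-02
1.400000000e+00	5.949797668e-02	4.555393586e-07	3.012430867e-05	5.952855653e-02	2.890444741e-02
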