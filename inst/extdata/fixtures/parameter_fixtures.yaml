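sustained:
  label: sustained
  provenance: rejection-sampled from default_ranges(), seed 20260930; label confirmed
    with fixed-step RK4 (step <= 0.05 s) at creation
  params:
    k1: 0.000145387519881
    k2: 0.004491768782206
    k3: 0.082412746027597
    k4: 0.003356275870765
    k5: 0.000361508050127
    k6: 0.000935588632664
    k7: 0.000667493438772
    k8: 0.00637875643751
    k9: 0.006527925448378
    k10: 0.003303975523485
    k11: 0.034568129297229
    k12: 0.010940613056505
    k13: 0.009361201575119
    k14: 3.633601442086989e-05
    k15: 49.879768114623133
    k16: 0.000455105458514
    k17: 0.000208794543131
    k18: 0.013107478674497
    k19: 0.000216809235916
    h: 2.0
transient:
  label: transient
  provenance: rejection-sampled from default_ranges(), seed 20260930; label confirmed
    with fixed-step RK4 (step <= 0.05 s) at creation
  params:
    k1: 1.417548755669539e-05
    k2: 0.014115174265964
    k3: 0.004079239871305
    k4: 0.003354507361536
    k5: 0.080795614333367
    k6: 2.708398282895186e-05
    k7: 0.001121558365434
    k8: 0.00013054192826
    k9: 0.000215051014589
    k10: 0.000898263940271
    k11: 0.339162479614656
    k12: 0.011953075740034
    k13: 0.038089013539323
    k14: 0.005652042897771
    k15: 0.088290365288939
    k16: 0.00502071112712
    k17: 1.873877548653637e-05
    k18: 0.000615455807399
    k19: 0.006900247324829
    h: 2.0
oscillatory:
  label: dampened_oscillatory
  provenance: rejection-sampled from default_ranges(), seed 20260930; label confirmed
    with fixed-step RK4 (step <= 0.05 s) at creation
  params:
    k1: 2.918926576883264e-05
    k2: 0.00427405130062
    k3: 2.394098483305218e-05
    k4: 4.592238454246899e-05
    k5: 0.96778290447311
    k6: 1.028116364610639e-05
    k7: 0.002689188869686
    k8: 0.000608063413889
    k9: 0.020306522883893
    k10: 0.000792397693627
    k11: 0.010425539817899
    k12: 0.005582696113368
    k13: 0.001849904220498
    k14: 6.463003266532491e-06
    k15: 10.066675719336395
    k16: 0.056786903857368
    k17: 0.000231885358944
    k18: 0.013897003487218
    k19: 0.000480422490898
    h: 2.0
unresponsive:
  label: unresponsive
  provenance: rejection-sampled from default_ranges(), seed 20260930; label confirmed
    with fixed-step RK4 (step <= 0.05 s) at creation
  params:
    k1: 0.002731108721143
    k2: 0.000713017903475
    k3: 0.00038345706235
    k4: 0.000593038384342
    k5: 0.000374284009024
    k6: 0.000289755973032
    k7: 0.000241350753836
    k8: 0.016068112967551
    k9: 0.013896842539987
    k10: 0.019018198429785
    k11: 1.252678071787034
    k12: 0.000646091950831
    k13: 0.037806524262332
    k14: 0.027156315228093
    k15: 0.192716874517499
    k16: 0.007663241155253
    k17: 0.00108855031736
    k18: 0.023616399052798
    k19: 7.930235051369342e-05
    h: 2.0
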