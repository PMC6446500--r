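gene	p_value	log_fc
g01	0.26399212423712015	-0.057245588500911521
g02	0.44045404577627778	-0.66428985462467238
g03	0.9639264012221247	-0.11072650010262557
g04	0.40198095655068755	2.107414297429135
g05	0.0065740009304136038	0.90881281713235917
g06	1.0000000000000001e-15	2.3741066023868704
g07	0.32337787607684731	-0.50132071883204876
g08	0.1720203182194382	0.7586025529570245
g09	0.74558217753656209	2.1167376183174809
g10	1.1438967429710122e-13	-3.0304393618211485
g11	0.37596679828129709	0.13587779603870767
g12	0.042928665643557906	0.49399042128747112
g13	0.79431038442999125	0.082392029258389898
g14	0.013000645392366648	1.6170868382153876
g15	0.43385317223146558	0.24424403276659357
g16	0.71493662288412452	0.28166207683197569
g17	0.87472943984903395	0.52943076043104909
g18	0.084553021704778075	-1.648660333247705
g19	0.41337677766568959	-1.4336356461678019
g20	0.34253158420324326	0.035088056474646932
g21	0.80973809841088951	0.36082850512648446
g22	0.095804574611750112	-2.2835144331205375
g23	0.8464896900113672	1.4966652709821282
g24	0.50031023588962853	-0.76093671099280424
g25	0.67900331364944577	-0.14063576596878799
g26	0.23158852197229862	-1.6106367879041479
g27	7.2127549345833733e-08	3.3809125092368086
g28	0.23662769887596369	0.38020300686069519
g29	0.0012691290395542151	2.5667701392450928
g30	0.5279834030661732	0.47746750649693848
g31	1.5626973959506645e-06	-1.9321003220946553
g32	3.3928508500733175e-12	-2.15880170652698
g33	0.51957231666892767	-1.5113522114123612
g34	0.51298466045409441	-0.0099517346492963774
g35	0.069614649517461658	-0.082042329896935343
g36	0.81958102714270353	-1.7780277344557394
g37	0.21500089718028903	-2.0392653926990065
g38	0.2278101637493819	0.95032204585601487
g39	0.84522152342833579	-0.78644288005244023
g40	0.54818415059708059	1.5005031544929945
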