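g01	g07
g01	g21
g01	g27
g01	g40
g02	g03
g02	g13
g03	g08
g03	g16
g03	g19
g03	g27
g04	g21
g04	g29
g04	g37
g04	g39
g04	g40
g05	g17
g05	g18
g05	g24
g05	g33
g05	g35
g06	g10
g06	g13
g06	g26
g06	g27
g06	g29
g06	g35
g06	g37
g07	g37
g08	g13
g08	g26
g08	g30
g08	g33
g08	g36
g09	g08
g09	g11
g09	g26
g10	g14
g10	g24
g10	g33
g11	g19
g11	g20
g11	g21
g11	g35
g11	g40
g12	g10
g12	g17
g12	g28
g12	g33
g13	g20
g13	g34
g14	g21
g14	g22
g14	g30
g14	g34
g15	g34
g15	g40
g16	g03
g16	g11
g16	g26
g16	g39
g17	g14
g17	g25
g18	g10
g18	g19
g18	g33
g19	g07
g19	g29
g19	g30
g20	g11
g20	g21
g20	g34
g20	g38
g21	g05
g21	g13
g21	g14
g21	g29
g21	g32
g21	g36
g22	g15
g22	g32
g23	g01
g23	g16
g23	g17
g23	g39
g24	g11
g24	g23
g24	g39
g25	g05
g25	g13
g25	g29
g25	g34
g26	g06
g26	g10
g27	g07
g27	g20
g27	g21
g27	g32
g28	g17
g28	g23
g29	g27
g29	g28
g29	g31
g30	g18
g30	g25
g30	g39
g31	g06
g31	g27
g32	g08
g32	g09
g32	g24
g32	g30
g32	g36
g33	g30
g34	g17
g34	g19
g35	g06
g35	g10
g35	g26
g35	g28
g35	g30
g35	g31
g35	g40
g36	g07
g36	g12
g36	g16
g37	g28
g38	g01
g38	g19
g40	g06
g40	g15
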