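cultivar,location_id,scenario,period,pbd_date
Yoshino,Washington DC,A1B,2020s,2001-04-01
Yoshino,Washington DC,A1B,2050s,2001-03-27
Yoshino,Washington DC,A1B,2080s,2001-03-22
Yoshino,Washington DC,A2,2020s,2001-03-31
Yoshino,Washington DC,A2,2050s,2001-03-19
Yoshino,Washington DC,A2,2080s,2001-03-04
Yoshino,Baltimore MD,A1B,2020s,2001-04-02
Yoshino,Baltimore MD,A1B,2050s,2001-03-28
Yoshino,Baltimore MD,A1B,2080s,2001-03-23
Yoshino,Baltimore MD,A2,2020s,2001-03-31
Yoshino,Baltimore MD,A2,2050s,2001-03-18
Yoshino,Baltimore MD,A2,2080s,2001-03-03
Yoshino,Kearneysville WV,A1B,2020s,2001-04-11
Yoshino,Kearneysville WV,A1B,2050s,2001-04-04
Yoshino,Kearneysville WV,A1B,2080s,2001-03-30
Yoshino,Kearneysville WV,A2,2020s,2001-04-07
Yoshino,Kearneysville WV,A2,2050s,2001-03-29
Yoshino,Kearneysville WV,A2,2080s,2001-03-11
Yoshino,Richmond VA,A1B,2020s,2001-03-18
Yoshino,Richmond VA,A1B,2050s,2001-03-14
Yoshino,Richmond VA,A1B,2080s,2001-03-13
Yoshino,Richmond VA,A2,2020s,2001-03-18
Yoshino,Richmond VA,A2,2050s,2001-03-07
Yoshino,Richmond VA,A2,2080s,2001-02-27
Kwanzan,Washington DC,A1B,2020s,2001-04-17
Kwanzan,Washington DC,A1B,2050s,2001-04-11
Kwanzan,Washington DC,A1B,2080s,2001-04-06
Kwanzan,Washington DC,A2,2020s,2001-04-13
Kwanzan,Washington DC,A2,2050s,2001-04-03
Kwanzan,Washington DC,A2,2080s,2001-03-17
Kwanzan,Baltimore MD,A1B,2020s,2001-04-18
Kwanzan,Baltimore MD,A1B,2050s,2001-04-12
Kwanzan,Baltimore MD,A1B,2080s,2001-04-07
Kwanzan,Baltimore MD,A2,2020s,2001-04-14
Kwanzan,Baltimore MD,A2,2050s,2001-04-03
Kwanzan,Baltimore MD,A2,2080s,2001-03-17
Kwanzan,Kearneysville WV,A1B,2020s,2001-04-26
Kwanzan,Kearneysville WV,A1B,2050s,2001-04-20
Kwanzan,Kearneysville WV,A1B,2080s,2001-04-14
Kwanzan,Kearneysville WV,A2,2020s,2001-04-21
Kwanzan,Kearneysville WV,A2,2050s,2001-04-12
Kwanzan,Kearneysville WV,A2,2080s,2001-03-24
Kwanzan,Richmond VA,A1B,2020s,2001-04-04
Kwanzan,Richmond VA,A1B,2050s,2001-03-30
Kwanzan,Richmond VA,A1B,2080s,2001-03-28
Kwanzan,Richmond VA,A2,2020s,2001-04-02
Kwanzan,Richmond VA,A2,2050s,2001-03-24
Kwanzan,Richmond VA,A2,2080s,2001-03-12
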