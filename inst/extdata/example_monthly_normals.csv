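location_id,scenario,period,month,tmax,tmin
Washington DC (example),A1B,2020s,1,7,-1
Washington DC (example),A1B,2020s,2,9,0
Washington DC (example),A1B,2020s,3,14,4
Washington DC (example),A1B,2020s,4,20,9
Washington DC (example),A1B,2020s,5,25,15
Washington DC (example),A1B,2020s,6,30,20
Washington DC (example),A1B,2020s,7,32,23
Washington DC (example),A1B,2020s,8,31,22
Washington DC (example),A1B,2020s,9,27,18
Washington DC (example),A1B,2020s,10,21,11
Washington DC (example),A1B,2020s,11,15,6
Washington DC (example),A1B,2020s,12,9,1
Washington DC (example),A1B,2050s,1,8,0
Washington DC (example),A1B,2050s,2,10,1
Washington DC (example),A1B,2050s,3,15,5
Washington DC (example),A1B,2050s,4,21,10
Washington DC (example),A1B,2050s,5,26,16
Washington DC (example),A1B,2050s,6,31,21
Washington DC (example),A1B,2050s,7,33,24
Washington DC (example),A1B,2050s,8,32,23
Washington DC (example),A1B,2050s,9,28,19
Washington DC (example),A1B,2050s,10,22,12
Washington DC (example),A1B,2050s,11,16,7
Washington DC (example),A1B,2050s,12,10,2
Washington DC (example),A1B,2080s,1,9,1
Washington DC (example),A1B,2080s,2,11,2
Washington DC (example),A1B,2080s,3,16,6
Washington DC (example),A1B,2080s,4,22,11
Washington DC (example),A1B,2080s,5,27,17
Washington DC (example),A1B,2080s,6,32,22
Washington DC (example),A1B,2080s,7,34,25
Washington DC (example),A1B,2080s,8,33,24
Washington DC (example),A1B,2080s,9,29,20
Washington DC (example),A1B,2080s,10,23,13
Washington DC (example),A1B,2080s,11,17,8
Washington DC (example),A1B,2080s,12,11,3
Washington DC (example),A2,2020s,1,7.2,-0.8
Washington DC (example),A2,2020s,2,9.2,0.2
Washington DC (example),A2,2020s,3,14.2,4.2
Washington DC (example),A2,2020s,4,20.2,9.2
Washington DC (example),A2,2020s,5,25.2,15.2
Washington DC (example),A2,2020s,6,30.2,20.2
Washington DC (example),A2,2020s,7,32.2,23.2
Washington DC (example),A2,2020s,8,31.2,22.2
Washington DC (example),A2,2020s,9,27.2,18.2
Washington DC (example),A2,2020s,10,21.2,11.2
Washington DC (example),A2,2020s,11,15.2,6.2
Washington DC (example),A2,2020s,12,9.2,1.2
Washington DC (example),A2,2050s,1,8.8,0.8
Washington DC (example),A2,2050s,2,10.8,1.8
Washington DC (example),A2,2050s,3,15.8,5.8
Washington DC (example),A2,2050s,4,21.8,10.8
Washington DC (example),A2,2050s,5,26.8,16.8
Washington DC (example),A2,2050s,6,31.8,21.8
Washington DC (example),A2,2050s,7,33.8,24.8
Washington DC (example),A2,2050s,8,32.8,23.8
Washington DC (example),A2,2050s,9,28.8,19.8
Washington DC (example),A2,2050s,10,22.8,12.8
Washington DC (example),A2,2050s,11,16.8,7.8
Washington DC (example),A2,2050s,12,10.8,2.8
Washington DC (example),A2,2080s,1,10.5,2.5
Washington DC (example),A2,2080s,2,12.5,3.5
Washington DC (example),A2,2080s,3,17.5,7.5
Washington DC (example),A2,2080s,4,23.5,12.5
Washington DC (example),A2,2080s,5,28.5,18.5
Washington DC (example),A2,2080s,6,33.5,23.5
Washington DC (example),A2,2080s,7,35.5,26.5
Washington DC (example),A2,2080s,8,34.5,25.5
Washington DC (example),A2,2080s,9,30.5,21.5
Washington DC (example),A2,2080s,10,24.5,14.5
Washington DC (example),A2,2080s,11,18.5,9.5
Washington DC (example),A2,2080s,12,12.5,4.5
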