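site,date,duration_h,tc_pct_pm25,tc_ugC_m3,d13c_permil,D14c_permil,levoglucosan_ng_m3,excluded
TRF,2019-08-02,24,32,4.5,-26.6,-489.9,NA,FALSE
TRF,2019-08-05,24,19,5.3,-26.7,-250.3,6.41,FALSE
TRF,2020-01-24,24,13,7.0,-25.6,-323.0,NA,FALSE
TRF,2020-02-07,24,16,5.3,-24.5,-382.9,66.52,FALSE
TRF,2020-02-13,23,10,5.3,-26.0,-441.2,44.94,FALSE
TRF,2020-02-20,24,16,8.7,-26.1,-360.2,62.92,FALSE
TRF,2020-02-21,24,11,6.4,-25.5,-349.6,NA,FALSE
TRF,2020-02-22,48,9,3.5,-25.0,-357.3,60.02,FALSE
TRF,2020-04-10,24,24,6.6,-23.2,-227.8,60.47,FALSE
TRF,2020-04-13,24,45,4.9,-25.0,-204.5,39.96,FALSE
TRF,2020-05-04,24,35,5.6,-25.5,-273.9,NA,FALSE
TRF,2020-05-21,24,42,3.8,-26.1,-381.8,18.94,FALSE
TRF,2020-07-08,24,22,3.9,-26.3,-536.2,9.57,FALSE
TRF,2020-08-18,24,15,3.4,-26.6,-576.4,8.95,FALSE
TRF,2020-09-14,24,29,3.2,-25.7,-514.0,13.98,FALSE
TRF,2020-10-13,24,34,4.1,-26.0,-373.2,37.92,FALSE
TRF,2020-10-14,24,29,4.3,-26.0,-311.4,NA,FALSE
TRF,2020-10-15,24,29,4.1,-26.6,-360.3,NA,FALSE
TRF,2020-10-16,24,26,4.7,-26.8,-410.3,51.68,FALSE
TRF,2020-11-14,48,7,3.0,-26.4,-375.0,34.74,FALSE
TRF,2020-12-11,24,10,7.3,-24.6,-494.9,53.08,FALSE
HUF,2020-02-20,24,20,8.6,-25.7,-417.2,65.82,FALSE
HUF,2020-10-13,24,49,5.4,-25.7,-370.0,40.00,FALSE
CRI,2020-02-21,24,17,8.2,-24.8,-433.8,NA,FALSE
CRI,2020-02-22,48,16,5.8,-25.1,-426.4,38.46,FALSE
CRI,2020-02-24,34,34,6.9,-26.0,-451.3,NA,FALSE
CRI,2020-10-14,23,66,5.4,-25.0,-421.3,NA,FALSE
CRI,2020-10-15,24,86,8.6,-25.9,-465.6,NA,FALSE
CRI,2020-10-16,24,61,10.4,-26.0,-467.5,61.11,FALSE
SNU,2019-01-14,24,19,25.6,-23.7,589.7,4.55,TRUE
SNU,2019-02-22,24,39,23.9,-23.6,-313.7,75.91,FALSE
SNU,2019-03-05,24,8,10.4,-23.7,-503.6,NA,FALSE
SNU,2019-04-22,24,28,10.0,-25.9,-239.3,9.69,FALSE
SNU,2019-05-24,24,29,14.7,-26.0,-430.1,NA,FALSE
SNU,2019-06-05,24,27,9.2,-25.8,-561.9,NA,FALSE
SNU,2019-07-17,24,14,7.4,-25.5,-370.6,NA,FALSE
SNU,2019-08-08,24,14,5.5,-26.1,-459.4,5.57,FALSE
SNU,2020-02-07,24,59,16.6,-23.6,-352.5,64.52,FALSE
SNU,2020-02-13,24,12,7.0,-25.2,-370.1,NA,FALSE
SNU,2020-04-10,24,58,16.4,-22.2,-284.9,66.24,FALSE
SNU,2020-04-13,24,50,7.0,-24.1,-290.5,38.25,FALSE
SNU,2020-05-04,24,69,11.0,-25.3,-400.0,NA,FALSE
SNU,2020-05-21,24,50,5.5,-26.2,-415.6,7.41,FALSE
SNU,2020-07-08,24,24,5.3,-25.7,-543.7,8.61,FALSE
SNU,2020-08-18,24,12,2.8,-27.3,-635.9,4.38,FALSE
SNU,2020-09-14,24,26,3.4,-26.1,-503.6,6.63,FALSE
SNU,2020-11-13,70,12,5.6,-25.3,-481.6,18.50,FALSE
SNU,2020-12-11,24,16,12.3,-24.6,-439.1,70.72,FALSE
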