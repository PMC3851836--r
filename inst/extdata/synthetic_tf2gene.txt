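# edge_class=TF2gene	regulator	target
TF01	G00080
TF01	G00011
TF01	G00085
TF01	G00063
TF01	G00118
TF01	G00007
TF01	G00095
TF01	G00107
TF01	G00092
TF01	G00037
TF01	G00083
TF01	G00068
TF01	G00089
TF01	G00040
TF01	G00087
TF01	G00105
TF01	G00023
TF01	G00117
TF01	G00013
TF01	G00082
TF01	G00004
TF01	G00114
TF01	G00101
TF01	G00065
TF01	G00070
TF02	G00051
TF02	G00032
TF02	G00043
TF02	G00104
TF02	G00083
TF02	G00084
TF02	G00090
TF02	G00063
TF02	G00006
TF02	G00011
TF02	G00074
TF02	G00110
TF02	G00069
TF02	G00029
TF02	G00001
TF02	G00023
TF02	G00050
TF02	G00026
TF02	G00067
TF02	G00027
TF02	G00071
TF02	G00118
TF02	G00109
TF02	G00033
TF02	G00062
TF03	G00004
TF03	G00041
TF03	G00113
TF03	G00025
TF03	G00063
TF03	G00037
TF03	G00053
TF03	G00070
TF03	G00107
TF03	G00047
TF03	G00026
TF03	G00039
TF03	G00027
TF03	G00049
TF03	G00087
TF03	G00021
TF03	G00077
TF03	G00075
TF03	G00106
TF03	G00017
TF03	G00069
TF03	G00102
TF03	G00024
TF03	G00062
TF03	G00104
TF04	G00059
TF04	G00076
TF04	G00067
TF04	G00077
TF04	G00101
TF04	G00096
TF04	G00115
TF04	G00020
TF04	G00071
TF04	G00117
TF04	G00053
TF04	G00062
TF04	G00002
TF04	G00107
TF04	G00087
TF04	G00043
TF04	G00114
TF04	G00049
TF04	G00074
TF04	G00090
TF04	G00065
TF04	G00029
TF04	G00094
TF04	G00023
TF04	G00006
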