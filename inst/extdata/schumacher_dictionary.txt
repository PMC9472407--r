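rsS00001
rsS00002
rsS00003
rsS00004
rsS00005
rsS00006
rsS00007
rsS00008
rsS00009
rsS00010
rsS00011
rsS00012
rsS00013
rsS00014
rsS00015
rsS00016
rsS00017
rsS00018
rsS00019
rsS00020
rsS00021
rsS00022
rsS00023
rsS00024
rsS00025
rsS00026
rsS00027
rsS00028
rsS00029
rsS00030
rsS00031
rsS00032
rsS00033
rsS00034
rsS00035
rsS00036
rsS00037
rsS00038
rsS00039
rsS00040
rsS00041
rsS00042
rsS00043
rsS00044
rsS00045
rsS00046
rsS00047
rsS00048
rsS00049
rsS00050
rsS00051
rsS00052
rsS00053
rsS00054
rsS00055
rsS00056
rsS00057
rsS00058
rsS00059
rsS00060
rsS00061
rsS00062
rsS00063
rsS00064
rsS00065
rsS00066
rsS00067
rsS00068
rsS00069
rsS00070
rsS00071
rsS00072
rsS00073
rsS00074
rsS00075
rsS00076
rsS00078
rsS00079
rsS00080
rsS00081
rsS00082
rsS00083
rsS00084
rsS00085
rsS00086
rsS00087
rsS00088
rsS00089
rsS00090
rsS00091
rsS00092
rsS00093
rsS00094
rsS00095
rsS00096
rsS00097
rsS00098
rsS00099
rsS00100
rsS00101
rsS00102
rsS00103
rsS00104
rsS00105
rsS00106
rsS00107
rsS00108
rsS00109
rsS00110
rsS00111
rsS00112
rsS00113
rsS00114
rsS00115
rsS00116
rsS00117
rsS00118
rsS00119
rsS00120
rsS00121
rsS00122
rsS00123
rsS00124
rsS00125
rsS00126
rsS00127
rsS00128
rsS00129
rsS00130
rsS00131
rsS00132
rsS00133
rsS00134
rsS00135
rsS00136
rsS00137
rsS00138
rsS00139
rsS00140
rsS00141
rsS00142
rsS00143
rsS00144
rsS00145
rsS00146
rsS00147
rsX00001
rsX00002
rsX00003
rsX00004
rsX00005
rsX00006
rsX00007
rsX00008
rsX00009
rsX00010
rsX00011
rsX00012
rsX00013
rsX00014
rsX00015
rsX00016
rsX00017
rsX00018
rsX00019
rsX00020
rsX00021
rsX00022
rsX00023
rsX00024
rsX00025
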