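table,compound,label,measured,calculated,error_ppm
4,4,[A]+,137.0603,137.0603,0
4,4,[A']+,137.0603,137.0603,0
4,6,[A]+,137.0599,137.0603,-2.92
4,6,[A']+,137.0599,137.0603,-2.92
4,6,[B]+,163.0755,163.0754,0.61
4,6,[M+H-A]+,223.0973,223.0965,3.55
4,8,[A]+,137.0601,137.0603,-1.46
4,8,[M+H-A]+,237.1117,237.1121,-1.69
4,10,[A]+,137.0604,137.0603,0.73
4,10,[A']+,151.0759,151.0754,3.31
4,10,[B]+,177.0923,177.0910,7.34
4,10,[M+H-A]+,237.1127,237.1121,2.53
4,11,[A]+,137.0607,137.0603,2.92
4,11,[A']+,137.0607,137.0603,2.92
4,11,[B]+,163.0762,163.0762,4.91
4,11,[M+H-A]+,223.0968,223.0965,1.35
4,14,[A]+,137.0599,137.0603,-2.92
4,14,[A']+,151.0753,151.0754,-0.66
5,1,[A']+,137.0607,137.0603,2.92
5,2,[A]+,137.0610,137.0603,5.12
5,2,[A']+,137.0610,137.0603,5.12
5,2,[C+H]+,233.0816,233.0808,3.43
5,3,[A]+,137.0602,137.0603,-0.73
5,3,[A']+,137.0602,137.0603,-0.73
5,3,[C+H]+,233.0812,233.0808,1.72
5,5,[A]+,137.0619,137.0603,11.67
5,5,[A']+,151.0775,151.0754,13.90
5,5,[C+H]+,247.0982,247.0965,6.88
5,7,[A]+,137.0605,137.0603,1.46
5,7,[A']+,151.0763,151.0754,5.96
5,7,[C+H]+,247.0973,247.0965,3.24
5,9,[A]+,137.0614,137.0603,8.03
5,9,[A']+,137.0614,137.0603,8.03
5,9,[C+H]+,233.0820,233.0808,5.15
5,12,[A]+,137.0613,137.0603,7.30
5,12,[A']+,151.0770,151.0754,10.59
5,12,[C+H]+,247.0977,247.0965,4.86
5,13,[A]+,137.0613,137.0603,7.30
5,13,[A']+,181.0861,181.0859,1.10
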