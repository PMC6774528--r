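province,belief,strip_outcome,n,mean_bt_expression,mean_pesticide
punjab,bt,all_negative,61,0.48,2.92
punjab,bt,at_least_one_positive,292,1.18,2.04
punjab,non_bt,all_negative,13,0.56,2.78
punjab,non_bt,at_least_one_positive,17,0.88,2.53
punjab,dont_know,all_negative,6,0.25,3.25
punjab,dont_know,at_least_one_positive,45,1.26,1.69
punjab,no_response,all_negative,0,NA,NA
punjab,no_response,at_least_one_positive,1,0.68,2.3
sindh,bt,all_negative,1,0,1.13
sindh,bt,at_least_one_positive,49,2.57,2.14
sindh,non_bt,all_negative,14,0.23,2.32
sindh,non_bt,at_least_one_positive,14,2.26,1.55
sindh,dont_know,all_negative,17,2.2,0
sindh,dont_know,at_least_one_positive,34,2.23,1.92
sindh,no_response,all_negative,0,NA,NA
sindh,no_response,at_least_one_positive,0,NA,NA
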