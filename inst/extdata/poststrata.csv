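geo_stratum,sex,age_group,intent,target_total
high_concentration,men,18-29,not_going,4105
high_concentration,men,18-29,going,3078
high_concentration,men,30-44,not_going,4078
high_concentration,men,30-44,going,5276
high_concentration,men,45+,not_going,3353
high_concentration,men,45+,going,3012
low_concentration,men,18-29,not_going,8693
low_concentration,men,18-29,going,19349
low_concentration,men,30-44,not_going,12818
low_concentration,men,30-44,going,18476
low_concentration,men,45+,not_going,10302
low_concentration,men,45+,going,22698
high_concentration,women,18-29,not_going,3159
high_concentration,women,18-29,going,1444
high_concentration,women,30-44,not_going,2267
high_concentration,women,30-44,going,2004
high_concentration,women,45+,not_going,1499
high_concentration,women,45+,going,994
low_concentration,women,18-29,not_going,4132
low_concentration,women,18-29,going,4658
low_concentration,women,30-44,not_going,9135
low_concentration,women,30-44,going,4356
low_concentration,women,45+,not_going,2687
low_concentration,women,45+,going,0
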