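category	years	note
isced_0	7	synthetic default mapping; replace with the study's own table
isced_1	9	synthetic default mapping; replace with the study's own table
isced_2	10	synthetic default mapping; replace with the study's own table
isced_3	13	synthetic default mapping; replace with the study's own table
isced_4	14	synthetic default mapping; replace with the study's own table
isced_5	16	synthetic default mapping; replace with the study's own table
isced_6	17	synthetic default mapping; replace with the study's own table
isced_7	19	synthetic default mapping; replace with the study's own table
isced_8	21	synthetic default mapping; replace with the study's own table
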