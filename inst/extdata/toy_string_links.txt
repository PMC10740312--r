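protein1 protein2 combined_score
P_gA1 P_gA2 955
P_gA1 P_gbio 930
P_gA2 P_gbio 945
P_gB1 P_gB2 910
P_gA1 P_gB1 400
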