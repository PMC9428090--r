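subject,condition,repeat,item,score
S01,quiet,1,immediate sound,6.5
S02,quiet,1,immediate sound,4.5
S03,quiet,1,immediate sound,5
S04,quiet,1,immediate sound,6.5
S05,quiet,1,immediate sound,5
S01,quiet,2,immediate sound,7
S02,quiet,2,immediate sound,5
S03,quiet,2,immediate sound,4
S04,quiet,2,immediate sound,5
S05,quiet,2,immediate sound,5
S01,conventional,1,immediate sound,7
S02,conventional,1,immediate sound,5
S03,conventional,1,immediate sound,3
S04,conventional,1,immediate sound,4
S05,conventional,1,immediate sound,9.5
S01,conventional,2,immediate sound,7
S02,conventional,2,immediate sound,6
S03,conventional,2,immediate sound,2
S04,conventional,2,immediate sound,3.5
S05,conventional,2,immediate sound,7.5
S01,quiet,1,delayed sound,4
S02,quiet,1,delayed sound,5
S03,quiet,1,delayed sound,5.5
S04,quiet,1,delayed sound,2
S05,quiet,1,delayed sound,5.5
S01,quiet,2,delayed sound,5.5
S02,quiet,2,delayed sound,5.5
S03,quiet,2,delayed sound,6.5
S04,quiet,2,delayed sound,3.5
S05,quiet,2,delayed sound,4.5
S01,conventional,1,delayed sound,7
S02,conventional,1,delayed sound,4.5
S03,conventional,1,delayed sound,9
S04,conventional,1,delayed sound,6
S05,conventional,1,delayed sound,7
S01,conventional,2,delayed sound,7
S02,conventional,2,delayed sound,5.5
S03,conventional,2,delayed sound,8
S04,conventional,2,delayed sound,4
S05,conventional,2,delayed sound,7.5
S01,quiet,1,comfort,8
S02,quiet,1,comfort,8
S03,quiet,1,comfort,8.5
S04,quiet,1,comfort,9.5
S05,quiet,1,comfort,7
S01,quiet,2,comfort,6.5
S02,quiet,2,comfort,7.5
S03,quiet,2,comfort,8.5
S04,quiet,2,comfort,8
S05,quiet,2,comfort,6.5
S01,conventional,1,comfort,8
S02,conventional,1,comfort,7.5
S03,conventional,1,comfort,7
S04,conventional,1,comfort,4.5
S05,conventional,1,comfort,3.5
S01,conventional,2,comfort,7.5
S02,conventional,2,comfort,7.5
S03,conventional,2,comfort,7
S04,conventional,2,comfort,5
S05,conventional,2,comfort,5
S01,quiet,1,overall,8.5
S02,quiet,1,overall,6.5
S03,quiet,1,overall,7.5
S04,quiet,1,overall,9
S05,quiet,1,overall,7
S01,quiet,2,overall,10
S02,quiet,2,overall,8
S03,quiet,2,overall,7.5
S04,quiet,2,overall,10
S05,quiet,2,overall,6
S01,conventional,1,overall,6
S02,conventional,1,overall,5.5
S03,conventional,1,overall,5.5
S04,conventional,1,overall,6
S05,conventional,1,overall,5
S01,conventional,2,overall,6
S02,conventional,2,overall,5.5
S03,conventional,2,overall,7.5
S04,conventional,2,overall,5.5
S05,conventional,2,overall,6
S01,quiet,1,willingness,6.5
S02,quiet,1,willingness,6
S03,quiet,1,willingness,7
S04,quiet,1,willingness,6.5
S05,quiet,1,willingness,8
S01,quiet,2,willingness,7
S02,quiet,2,willingness,6.5
S03,quiet,2,willingness,8
S04,quiet,2,willingness,8
S05,quiet,2,willingness,9
S01,conventional,1,willingness,5.5
S02,conventional,1,willingness,6.5
S03,conventional,1,willingness,8.5
S04,conventional,1,willingness,6.5
S05,conventional,1,willingness,7
S01,conventional,2,willingness,6.5
S02,conventional,2,willingness,6.5
S03,conventional,2,willingness,8.5
S04,conventional,2,willingness,7
S05,conventional,2,willingness,6.5
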