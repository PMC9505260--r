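predictor	domain	model_1	model_2	model_3	model_4	model_5
AlphaFold	NBD	83.3	85.3	86.8	83.5	85.7
AlphaFold	HD1	82.8	84.9	85.4	82.1	84.3
AlphaFold	WHD	70.2	71.5	74.2	71.0	71.2
AlphaFold	HD2	76.8	78.6	79.4	77.2	79.5
AlphaFold	LRR	84.6	85.0	86.4	85.3	84.7
AlphaFold	Whole	79.1	80.3	81.4	79.1	79.8
RoseTTAFold	NBD	83.4	81.6	82.5	80.7	79.5
RoseTTAFold	HD1	83.5	82.3	81.3	80.7	80.3
RoseTTAFold	WHD	80.0	78.4	76.4	78.7	77.3
RoseTTAFold	HD2	75.2	73.1	70.2	73.0	71.1
RoseTTAFold	LRR	82.3	82.9	83.1	81.9	81.8
RoseTTAFold	Whole	79.7	79.4	77.9	77.6	76.8
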