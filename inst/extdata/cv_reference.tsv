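fold	mPrecision	mRecall	mACC	mF1
1	0.882	0.861	0.970	0.871
2	0.946	0.958	0.970	0.948
3	0.976	0.916	0.970	0.937
4	0.883	0.857	0.970	0.870
5	0.977	0.9648	0.972	0.970
6	0.8795	0.870	0.971	0.875
7	0.876	0.862	0.970	0.869
8	0.879	0.856	0.968	0.867
9	0.980	0.964	0.969	0.971
10	0.880	0.864	0.969	0.871
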