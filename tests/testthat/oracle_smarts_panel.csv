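title,mw,hbd,hba
lib_0001_et-cl,64.515,0,0
lib_0002_ph-et-keto-conh2,205.257,1,2
lib_0003_keto-nme2,101.149,0,1
lib_0004_et-ph-ph-et-nme2,253.389,0,0
lib_0005_keto-et-ph-keto-ph-cooh,338.403,1,4
lib_0006_keto-et-et-et-oh,172.268,1,2
lib_0007_ph-ph-ph-et-eth-oh,304.389,1,2
lib_0008_et-so2nh-keto-cooh,209.223,2,6
lib_0009_keto-conh2,101.105,1,2
lib_0010_ph-keto-me,148.205,0,1
lib_0011_keto-et-nme2,129.203,0,1
lib_0012_ph-et-eth-oh,152.193,1,2
lib_0013_ph-conh2,121.139,1,1
lib_0014_et-keto-keto-so2nh-keto-cooh,321.351,2,8
lib_0015_keto-eth-et-cooh,146.142,1,4
lib_0016_ph-et-keto-keto-so2nh-keto-cooh,397.449,2,8
lib_0017_ph-me,92.141,0,0
lib_0018_keto-eth-et-ph-oh,208.257,1,3
lib_0019_et-cl,64.515,0,0
lib_0020_et-so2nh-oh,139.176,2,4
lib_0021_keto-keto-ph-et-keto-et-oh,332.44,1,4
lib_0022_keto-eth-et-so2nh-keto-nme2,280.346,1,6
lib_0023_et-ph-et-et-et-eth-oh,236.355,1,2
lib_0024_keto-oh,88.106,1,2
lib_0025_keto-eth-keto-conh2,173.168,1,4
lib_0026_keto-et-so2nh-keto-so2nh-me,314.385,2,8
lib_0027_et-nme2,73.139,0,0
lib_0028_keto-keto-ph-ph-keto-oh,352.43,1,4
lib_0029_et-et-oh,88.15,1,1
lib_0030_et-et-et-et-ph-et-oh,248.41,1,1
lib_0031_et-et-eth-me,88.15,0,1
lib_0032_ph-et-keto-nme2,205.301,0,1
lib_0033_ph-oh,108.14,1,1
lib_0034_et-ph-ph-keto-keto-eth-oh,340.419,1,4
lib_0035_keto-et-et-cooh,158.197,1,3
lib_0036_keto-et-et-keto-so2nh-et-oh,307.412,2,6
lib_0037_et-eth-keto-so2nh-keto-ph-me,327.402,1,6
lib_0038_ph-keto-cooh,178.187,1,3
lib_0039_et-ph-ph-keto-ph-et-cl,376.927,0,1
lib_0040_ph-ph-keto-me,224.303,0,1
lib_0041_et-eth-keto-keto-oh,188.223,1,4
lib_0042_keto-keto-eth-oh,160.169,1,4
lib_0043_et-keto-eth-keto-et-me,200.278,0,3
lib_0044_keto-ph-et-ph-me,252.357,0,1
lib_0045_et-eth-me,60.096,0,1
lib_0046_keto-nme2,101.149,0,1
lib_0047_ph-et-nme2,149.237,0,0
lib_0048_keto-keto-keto-eth-me,200.234,0,4
lib_0049_et-me,44.097,0,0
lib_0050_keto-et-so2nh-oh,195.24,2,5
lib_0051_et-ph-oh,136.194,1,1
lib_0052_et-et-so2nh-keto-so2nh-oh,302.374,3,8
lib_0053_ph-keto-et-so2nh-keto-oh,327.402,2,6
lib_0054_ph-et-eth-keto-cl,212.676,0,2
lib_0055_keto-oh,88.106,1,2
lib_0056_et-eth-et-cl,108.568,0,1
lib_0057_et-et-so2nh-et-cl,199.703,1,3
lib_0058_et-oh,60.096,1,1
lib_0059_keto-so2nh-et-so2nh-me,258.321,2,7
lib_0060_keto-eth-oh,104.105,1,3
lib_0061_keto-me,72.107,0,1
lib_0062_keto-eth-keto-eth-oh,176.168,1,5
lib_0063_keto-eth-et-eth-et-conh2,189.211,1,4
lib_0064_ph-ph-keto-eth-keto-keto-cl,372.848,0,4
lib_0065_ph-conh2,121.139,1,1
lib_0066_ph-ph-conh2,197.237,1,1
lib_0067_keto-keto-et-ph-et-me,260.377,0,2
lib_0068_ph-et-conh2,149.193,1,1
lib_0069_ph-ph-keto-eth-me,240.302,0,2
lib_0070_ph-keto-et-so2nh-me,255.339,1,4
lib_0071_et-et-so2nh-keto-oh,223.294,2,5
lib_0072_et-cl,64.515,0,0
lib_0073_et-et-keto-nme2,157.257,0,1
lib_0074_keto-et-keto-ph-keto-cooh,318.369,1,5
lib_0075_et-keto-eth-keto-me,172.224,0,3
lib_0076_keto-eth-keto-cooh,174.152,1,5
lib_0077_keto-eth-et-cooh,146.142,1,4
lib_0078_ph-et-eth-keto-nme2,221.3,0,2
lib_0079_keto-ph-keto-eth-et-me,248.322,0,3
lib_0080_keto-so2nh-et-keto-cl,255.723,1,5
lib_0081_keto-conh2,101.105,1,2
lib_0082_keto-et-ph-oh,192.258,1,2
lib_0083_et-ph-me,120.195,0,0
lib_0084_et-keto-eth-oh,132.159,1,3
lib_0085_ph-cooh,122.123,1,2
lib_0086_ph-et-ph-keto-et-me,280.411,0,1
lib_0087_keto-ph-me,148.205,0,1
lib_0088_keto-et-so2nh-et-et-eth-oh,267.347,2,6
lib_0089_ph-keto-et-eth-et-cl,240.73,0,2
lib_0090_keto-cooh,102.089,1,3
lib_0091_ph-oh,108.14,1,1
lib_0092_ph-et-ph-conh2,225.291,1,1
lib_0093_et-keto-cooh,130.143,1,3
lib_0094_keto-so2nh-keto-nme2,236.293,1,5
lib_0095_ph-ph-conh2,197.237,1,1
lib_0096_et-et-et-et-nme2,157.301,0,0
lib_0097_et-keto-et-ph-oh,220.312,1,2
lib_0098_et-cooh,74.079,1,2
lib_0099_keto-et-eth-keto-me,172.224,0,3
lib_0100_ph-et-keto-so2nh-et-conh2,312.391,2,5
lib_0101_keto-eth-et-nme2,145.202,0,2
lib_0102_et-nme2,73.139,0,0
lib_0103_ph-keto-et-me,176.259,0,1
lib_0104_keto-ph-cooh,178.187,1,3
lib_0105_et-keto-eth-me,116.16,0,2
lib_0106_ph-et-eth-et-eth-oh,196.246,1,3
lib_0107_keto-ph-et-keto-ph-keto-nme2,393.527,0,3
lib_0108_ph-ph-keto-conh2,253.301,1,2
lib_0109_ph-ph-ph-ph-et-keto-cl,424.971,0,1
lib_0110_et-keto-ph-oh,192.258,1,2
lib_0111_keto-keto-eth-et-ph-et-nme2,305.418,0,3
lib_0112_et-et-et-et-keto-keto-nme2,269.429,0,2
lib_0113_keto-ph-et-eth-keto-nme2,277.364,0,3
lib_0114_keto-eth-me,88.106,0,2
lib_0115_keto-so2nh-et-eth-keto-eth-me,267.303,1,7
lib_0116_keto-nme2,101.149,0,1
lib_0117_ph-keto-et-keto-me,232.323,0,2
lib_0118_keto-ph-cooh,178.187,1,3
lib_0119_ph-keto-eth-et-et-oh,236.311,1,3
lib_0120_ph-et-cooh,150.177,1,2
lib_0121_keto-keto-et-keto-me,212.289,0,3
lib_0122_et-eth-et-cl,108.568,0,1
lib_0123_et-me,44.097,0,0
lib_0124_keto-ph-keto-ph-et-eth-me,324.42,0,3
lib_0125_ph-keto-ph-ph-oh,316.4,1,2
lib_0126_ph-ph-keto-me,224.303,0,1
lib_0127_keto-keto-et-ph-ph-keto-me,364.485,0,3
lib_0128_keto-eth-et-so2nh-et-et-cooh,281.33,2,7
lib_0129_keto-so2nh-keto-so2nh-keto-ph-oh,434.492,3,10
lib_0130_et-ph-ph-oh,212.292,1,1
lib_0131_et-conh2,73.095,1,1
lib_0132_et-et-et-eth-oh,132.203,1,2
lib_0133_ph-et-so2nh-et-ph-conh2,332.425,2,4
lib_0134_ph-conh2,121.139,1,1
lib_0135_et-et-eth-keto-et-keto-conh2,257.33,1,4
lib_0136_ph-et-ph-cooh,226.275,1,2
lib_0137_ph-ph-keto-cooh,254.285,1,3
lib_0138_et-eth-me,60.096,0,1
lib_0139_et-so2nh-et-conh2,180.229,2,4
lib_0140_et-et-eth-keto-et-conh2,201.266,1,3
lib_0141_et-eth-et-eth-et-cl,152.621,0,2
lib_0142_ph-et-ph-keto-so2nh-me,331.437,1,4
lib_0143_et-ph-ph-conh2,225.291,1,1
lib_0144_keto-et-et-conh2,157.213,1,2
lib_0145_et-so2nh-et-et-keto-nme2,264.391,1,4
lib_0146_ph-ph-keto-keto-me,280.367,0,2
lib_0147_keto-so2nh-et-nme2,208.283,1,4
lib_0148_ph-oh,108.14,1,1
lib_0149_ph-et-nme2,149.237,0,0
lib_0150_et-so2nh-et-ph-ph-ph-conh2,408.523,2,4
lib_0151_ph-ph-keto-nme2,253.345,0,1
lib_0152_et-eth-me,60.096,0,1
lib_0153_et-so2nh-et-et-conh2,208.283,2,4
lib_0154_keto-et-eth-keto-keto-cooh,258.27,1,6
lib_0155_keto-keto-ph-ph-keto-so2nh-me,415.511,1,6
lib_0156_keto-et-keto-eth-et-eth-me,216.277,0,4
lib_0157_et-cl,64.515,0,0
lib_0158_ph-keto-so2nh-me,227.285,1,4
lib_0159_et-et-so2nh-oh,167.23,2,4
lib_0160_ph-et-cl,140.613,0,0
lib_0161_et-eth-me,60.096,0,1
lib_0162_keto-cooh,102.089,1,3
lib_0163_keto-eth-et-ph-ph-ph-oh,360.453,1,3
lib_0164_ph-keto-keto-so2nh-me,283.349,1,5
lib_0165_et-so2nh-oh,139.176,2,4
lib_0166_ph-cooh,122.123,1,2
lib_0167_keto-oh,88.106,1,2
lib_0168_keto-eth-et-eth-oh,148.158,1,4
lib_0169_ph-conh2,121.139,1,1
lib_0170_ph-conh2,121.139,1,1
lib_0171_et-cooh,74.079,1,2
lib_0172_keto-me,72.107,0,1
lib_0173_et-keto-et-so2nh-keto-so2nh-me,342.439,2,8
lib_0174_keto-ph-conh2,177.203,1,2
lib_0175_ph-keto-keto-me,204.269,0,2
lib_0176_et-so2nh-et-eth-oh,183.229,2,5
lib_0177_et-ph-oh,136.194,1,1
lib_0178_et-keto-me,100.161,0,1
lib_0179_ph-ph-keto-me,224.303,0,1
lib_0180_ph-et-keto-et-et-ph-oh,324.464,1,2
lib_0181_keto-keto-so2nh-et-et-conh2,292.357,2,6
lib_0182_keto-conh2,101.105,1,2
lib_0183_et-nme2,73.139,0,0
lib_0184_et-eth-me,60.096,0,1
lib_0185_keto-cl,92.525,0,1
lib_0186_et-et-so2nh-oh,167.23,2,4
lib_0187_ph-keto-so2nh-me,227.285,1,4
lib_0188_keto-et-keto-eth-keto-cl,248.706,0,4
lib_0189_ph-ph-ph-ph-oh,336.434,1,1
lib_0190_keto-eth-keto-eth-keto-cooh,246.215,1,7
lib_0191_et-so2nh-me,123.177,1,3
lib_0192_keto-so2nh-keto-so2nh-keto-eth-oh,374.393,3,11
lib_0193_ph-ph-et-keto-et-nme2,309.453,0,1
lib_0194_ph-ph-ph-et-ph-me,348.489,0,0
lib_0195_ph-cooh,122.123,1,2
lib_0196_et-ph-cooh,150.177,1,2
lib_0197_ph-ph-me,168.239,0,0
lib_0198_ph-ph-ph-me,244.337,0,0
lib_0199_keto-keto-keto-keto-keto-et-nme2,353.459,0,5
lib_0200_keto-eth-oh,104.105,1,3
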