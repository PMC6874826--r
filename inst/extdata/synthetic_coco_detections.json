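[{"image_id":1,"category_id":1,"bbox":[1035.5,26.7,76.2,93.2],"score":0.707},{"image_id":1,"category_id":1,"bbox":[26.4,337.9,57.8,59.9],"score":0.9508},{"image_id":1,"category_id":1,"bbox":[44.5,344.1,60.1,85.4],"score":0.3631},{"image_id":1,"category_id":1,"bbox":[549.2,533.6,55.7,52.4],"score":0.3182},{"image_id":2,"category_id":1,"bbox":[919.5,672.8,149.3,129.8],"score":0.5865},{"image_id":2,"category_id":1,"bbox":[1211.8,848.2,103,97.6],"score":0.6044},{"image_id":2,"category_id":1,"bbox":[217.1,915.5,128.4,131.3],"score":0.7002},{"image_id":2,"category_id":2,"bbox":[771.3,83.8,76.1,58.5],"score":0.288},{"image_id":2,"category_id":1,"bbox":[482,580.3,62.7,97.1],"score":0.4042},{"image_id":3,"category_id":1,"bbox":[86.6,555.8,87.5,71.5],"score":0.7196},{"image_id":3,"category_id":1,"bbox":[718.2,613,63.5,88.7],"score":0.6753},{"image_id":3,"category_id":1,"bbox":[138.6,180.2,132.5,139.8],"score":0.7109},{"image_id":3,"category_id":1,"bbox":[199.6,483.3,122.7,62.2],"score":0.4434},{"image_id":3,"category_id":1,"bbox":[1339.9,483.1,92,104.6],"score":0.9591},{"image_id":3,"category_id":1,"bbox":[719.5,101.9,108.6,60],"score":0.2844},{"image_id":3,"category_id":2,"bbox":[561.1,971.1,114,71.8],"score":0.405},{"image_id":3,"category_id":1,"bbox":[1527.4,586.5,102.4,59.3],"score":0.5564},{"image_id":4,"category_id":1,"bbox":[1021.8,102.8,54,131],"score":0.8593},{"image_id":4,"category_id":1,"bbox":[1016,110.6,65.9,134.5],"score":0.4168},{"image_id":4,"category_id":1,"bbox":[1305.2,954.4,121,132.6],"score":0.9087},{"image_id":4,"category_id":1,"bbox":[1267.6,365.6,76.5,69.9],"score":0.8095},{"image_id":4,"category_id":1,"bbox":[380.9,403.1,69.6,122.8],"score":0.9147},{"image_id":4,"category_id":1,"bbox":[1169.1,776.1,97.2,69.5],"score":0.9388},{"image_id":4,"category_id":1,"bbox":[1143.3,568.7,132.9,132.4],"score":0.8543},{"image_id":4,"category_id":2,"bbox":[1580.6,717.6,116,128.7],"score":0.7448},{"image_id":4,"category_id":2,"bbox":[1606.8,719.2,117.4,125.9],"score":0.4918},{"image_id":4,"category_id":2,"bbox":[768.8,683.9,88.5,122.7],"score":0.7901},{"image_id":4,"category_id":1,"bbox":[532.8,568.7,106.7,54.3],"score":0.6939},{"image_id":5,"category_id":1,"bbox":[877.8,752.4,127.1,78.6],"score":0.9507},{"image_id":5,"category_id":1,"bbox":[902.7,699.1,109.9,130],"score":0.9836},{"image_id":5,"category_id":1,"bbox":[109.9,668,83.5,51.7],"score":0.5883},{"image_id":5,"category_id":1,"bbox":[100.8,697.4,85.8,62.1],"score":0.4467},{"image_id":5,"category_id":1,"bbox":[505,209.9,70.1,111.4],"score":0.6791},{"image_id":5,"category_id":2,"bbox":[1425.1,784.2,99.7,110.5],"score":0.7824},{"image_id":5,"category_id":1,"bbox":[406.2,562.3,64.3,70.6],"score":0.3918}]
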