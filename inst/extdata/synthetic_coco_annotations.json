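{"images":[{"id":1,"width":1920,"height":1080},{"id":2,"width":1920,"height":1080},{"id":3,"width":1920,"height":1080},{"id":4,"width":1920,"height":1080},{"id":5,"width":1920,"height":1080}],"annotations":[{"id":1,"image_id":1,"category_id":1,"bbox":[1026.8,25.1,71.2,82.9],"area":5902.48,"iscrowd":0},{"id":2,"image_id":1,"category_id":1,"bbox":[32.2,339.7,60.1,85.4],"area":5132.54,"iscrowd":0},{"id":3,"image_id":1,"category_id":1,"bbox":[814,356.2,98.2,120.4],"area":11823.28,"iscrowd":0},{"id":4,"image_id":2,"category_id":1,"bbox":[933,679.5,136.7,130.9],"area":17894.03,"iscrowd":0},{"id":5,"image_id":2,"category_id":1,"bbox":[1207.1,855.3,97.2,105.8],"area":10283.76,"iscrowd":0},{"id":6,"image_id":2,"category_id":1,"bbox":[205.4,921.8,122.5,137],"area":16782.5,"iscrowd":0},{"id":7,"image_id":3,"category_id":1,"bbox":[94.6,556.9,85.8,73.5],"area":6306.3,"iscrowd":0},{"id":8,"image_id":3,"category_id":1,"bbox":[728.8,634.1,63.3,92.9],"area":5880.57,"iscrowd":0},{"id":9,"image_id":3,"category_id":1,"bbox":[135.1,188,111.3,132.9],"area":14791.77,"iscrowd":0},{"id":10,"image_id":3,"category_id":1,"bbox":[222.7,514.4,122.7,62.2],"area":7631.94,"iscrowd":0},{"id":11,"image_id":3,"category_id":1,"bbox":[1346,473.7,67.9,124.2],"area":8433.18,"iscrowd":0},{"id":12,"image_id":4,"category_id":1,"bbox":[1030.2,114.6,65.9,134.5],"area":8863.55,"iscrowd":0},{"id":13,"image_id":4,"category_id":1,"bbox":[1313.8,939.2,99.7,130.3],"area":12990.91,"iscrowd":0},{"id":14,"image_id":4,"category_id":1,"bbox":[1263.3,373.2,63.3,66.1],"area":4184.13,"iscrowd":0},{"id":15,"image_id":4,"category_id":1,"bbox":[377.4,403.9,80.5,117.8],"area":9482.9,"iscrowd":0},{"id":16,"image_id":4,"category_id":1,"bbox":[1166,775.4,111.9,62.2],"area":6960.18,"iscrowd":0},{"id":17,"image_id":4,"category_id":1,"bbox":[1155.8,568.5,129.6,122.5],"area":15876,"iscrowd":0},{"id":18,"image_id":4,"category_id":2,"bbox":[1574.4,709.7,117.4,125.9],"area":14780.66,"iscrowd":0},{"id":19,"image_id":4,"category_id":2,"bbox":[760.2,675.9,87.5,119.9],"area":10491.25,"iscrowd":0},{"id":20,"image_id":5,"category_id":1,"bbox":[882.9,760.2,134.7,63.8],"area":8593.86,"iscrowd":0},{"id":21,"image_id":5,"category_id":1,"bbox":[899.7,704.5,104.1,134.1],"area":13959.81,"iscrowd":0},{"id":22,"image_id":5,"category_id":1,"bbox":[384.3,517.5,110.7,78.1],"area":8645.67,"iscrowd":0},{"id":23,"image_id":5,"category_id":1,"bbox":[103.3,684,85.8,62.1],"area":5328.18,"iscrowd":0},{"id":24,"image_id":5,"category_id":1,"bbox":[509.7,212.1,86.3,113.3],"area":9777.79,"iscrowd":0},{"id":25,"image_id":5,"category_id":2,"bbox":[1420.2,775.6,89,88.9],"area":7912.1,"iscrowd":0}],"categories":[{"id":1,"name":"seedling"},{"id":2,"name":"weed"}]}
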