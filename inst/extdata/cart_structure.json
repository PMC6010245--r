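{"tree":{"leaf":false,"feature":"n_holes","threshold":1.5,"left_op":"lt","n":240,"left":{"leaf":true,"class":"central_vein","n":120},"right":{"leaf":true,"class":"portal_tract","n":120}},"features":["n_holes","total_hole_area_um2","max_hole_area_um2","collagen_area_um2"],"classes":["central_vein","portal_tract"]}
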