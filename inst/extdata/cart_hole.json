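{"tree":{"leaf":false,"feature":"surrounding_collagen_um2","threshold":41.5802001953125,"left_op":"lt","n":634,"left":{"leaf":true,"class":"other","n":193},"right":{"leaf":false,"feature":"length_um","threshold":29.1651391133765,"left_op":"ge","n":441,"left":{"leaf":true,"class":"other","n":8},"right":{"leaf":false,"feature":"density","threshold":10.5,"left_op":"ge","n":433,"left":{"leaf":true,"class":"other","n":5},"right":{"leaf":true,"class":"vessel_or_duct","n":428}}}},"features":["density","width_um","length_um","solidity","surrounding_collagen_um2"],"classes":["other","vessel_or_duct"]}
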