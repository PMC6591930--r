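provider	kind	month	n
patent	regular	1	30475
patent	regular	2	1287
patent	irregular	1	9085
patent	irregular	2	20000
abstract	regular	1	15100
abstract	regular	2	30710
abstract	irregular	1	8274
abstract	irregular	2	45800
pubmed	regular	1	24710
pubmed	regular	2	16000
pubmed	irregular	1	6663
pubmed	irregular	2	86325
mix	irregular	1	200
mix	irregular	2	24000
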