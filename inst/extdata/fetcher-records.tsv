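id	name	taxid	organism_name	sequence	aliases	xrefs
P00001	Synthetic kinase alpha	9606	human	MKTAYIAKQRQISFVKSHFSRQLEERLGLIEV	gene1;kin-alpha	refseq:NP_000001;intact:EBI-10001
P00002	Synthetic kinase beta	9606	human	MSDLELKLRQTSYAVHQPNELIAKWFGERVID	gene2;kin-beta	refseq:NP_000002;intact:EBI-10002
P00003	Synthetic phosphatase	10090	mouse	MADEEKLPPGWEKRMSRSSGRVYYFNHITNAS	gene3	refseq:NP_000003
P00004	Synthetic adaptor	4932	yeast	MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEY	gene4;adp1	intact:EBI-10004
P00005	Synthetic scaffold	562	ecoli	MKKLVLSLSLVLAFSSATAAFAAIPQNIRIGT	gene5	refseq:NP_000005
P00006	Synthetic chaperone	9606	human	MGKDYYQTLGLARGASDEEIKRAYRRQALRYH	gene6;chp6	refseq:NP_000006;intact:EBI-10006
P00007	Synthetic protease	9606	human	MALWMRLLPLLALLALWGPDPAAAFVNQHLCG	gene7	intact:EBI-10007
P00008	Synthetic ligase	10090	mouse	MSTNPKPQRKTKRNTNRRPQDVKFPGGGQIVG	gene8	refseq:NP_000008
P00009	Synthetic receptor	9606	human	MEEPQSDPSVEPPLSQETFSDLWKLLPENNVL	gene9;rcp9	refseq:NP_000009
P00010	Synthetic transporter	4932	yeast	MAEGEITTFTALTEKFNLPPGNYKKPKLLYCS	gene10	intact:EBI-10010
P00011	Synthetic polymerase	562	ecoli	MNIFEMLRIDEGLRLKIYKDTEGYYTIGIGHL	gene11	refseq:NP_000011
P00012	Synthetic helicase	9606	human	MVLSEGEWQLVLHVWAKVEADVAGHGQDILIR	gene12;hel12	refseq:NP_000012;intact:EBI-10012
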