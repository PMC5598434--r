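>fbox_ref_1
WKQRRYHVEFAPIVTQSGWTKVTFPPASRHRNHSYGTHKSRRFNQCKNGWDKDTYNWSLY
YESAVAHEDWPVQDLSEIFNFKRQKRHLQEFCSNWTFFSWNSRAYAAVWAKIFEAGEGIT
KNTVFHFFIQWKGKRQEHPQTDEGGEHWEGGHTPRDFATYLAADFLKGHYFEEICRGSYW
ASGCEHCAVPFHVSRPAWYNEDAEEIYWIYAPTSAVCQVRCPDIIWDRCHEYILVPQTYG
RVTYQELSTCSQLIGQIQKSHDELDKVVANFECHHTQCNFLAHGIRYFASCKDYQYYCSD
AGSTDCLGDLEDKDTCPGDLHHADAGIVSNQHTWQNYSSGPFPKCLLQCRLDPLTSVQYD
STHAAIDDWWQYSCNAYKHLFYVGVEECFSKCAIVIWIWAGRSAHVYPWIAGYDDRTDER
GIHPHRRCVKKDGWDDIRNRWHGNFGECTFNCVELTPARRPRHDEHHVDEESYEAYPHKV
LYGDCQAPNEKWVYREFNLNRPSEAKEWKEKGHEVHAAREREYEIQHQNKGQCCENKTTL
QWPTVKTAAGHPQCPGYDRYQWWWHGKKEWSAFTPFGRGHSCVFKEYFDLGVQEPASF
>fbox_ref_2
RNAGQEPNNTCISLDKCNFITTNPCFHVGNGTQDSIYQLNAVANNHFLTNFSIKPLFWAS
FFPGCTGHHSKTESGHCYFLVPFACWLTLHDPHDTDWPEFKENSKHIWVCQFEVHSPKIQ
KGQFSIQHIDRALTLYVRRDKISHALKDEWSQFWQPVKCFTKVLCIIIGCDWYWGKCWFW
NIYCATTTFEHNDQAGRELNPVFRQQVARVWVYFEQFEFEGGCERFVNWVKYLPIYTKWN
VGDWPGTIKWLHQQVVSIQGHSQIFRWSVDKAHYKCAYSPFRISEPKHVQIINFTLQPNL
HENQDHQRWEGEDRQVKLYIHRCCHVHIWSSPFSKCGSPPFDAITLIIPYKQLARVRALY
TWYVQFHSEQLFVRKSWFTIDLGATLHWDWSPPLHGGCNTGWNVCKYWLTGNDDGCSRQC
HEWTQEQAAILCADKVGDLQKDEEHQVKNQEHYRQEHEARARCNIWYITYGPHKYSWVIG
SNYEGGRRFDIYHFLIGLDWTRLLETHQNPCFATDGYAGHDGHQGSFHYKTYKHFAFWCH
NCYQCWEHSHRKHHPKTLAVFELNDIRSNVVIWYSATQLSFQDKENISHAFQKIHFYE
>fbox_ref_3
CSESKGNLIFEYATWVPRWNHHLTWWLDAKGVRQDWTVCIKFSSHIQFYNFQVVSECTFN
CPNSKEWHCDETFTYRIGFLIRNGFEDAACKNPLNNEQFWVWHYSGPVAWAHWNGWNPCW
ERAEEWCWVWHSIYGKYQFDQKHFYESSYVTKISNLCKFSVEFFFRNEKTRDWCDYRCDI
STSSISVPPENAANYSNQPRCVEIEYSLVYFEGWWIGIAFGSCDEALYKRWTYWHCQSLC
WGKGEQCEWPYLGTFCAHWYKDRFTQFTFVEGNHLSGINFGCIFYSNRWDWRYPEHRPIG
RKEKWDHFYLIESQAKGVHGHEVQHAACYPQINELCYNILHLYNYHQTWLPQRCTCLHFQ
LAYLLQLCHRVVSTGEYVEIVQELWSLGCAVRYQEYQAAPPLCHYIFKSRLGRDCFYRNW
LFSCAFGGIPTEVVASSRQDIVYQHKTPRADSLKAQKLKSVSESNKWLCDRILPTAVCCH
TGAELDGDDNCVIEDLVENDFEGGVPYKHLPTISYDIDQGESTLRCWDAHHAYRTDHVWT
INKYTATQYQWPSYPNWICRAHFTVNGKLWVVYTFLIIYVIHEPKDPIFIHNFTAHSL
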