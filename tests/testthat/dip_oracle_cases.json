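[{"x": [0.0, 0.0, 1.0, 1.0], "dip": 0.25}, {"x": [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0], "dip": 0.04999999999999993}, {"x": [1.0, 1.0, 1.0, 2.0, 1.0, 0.0], "dip": 0.08333333333333333}, {"x": [0.9, 0.3, 0.2, 0.2, 0.4], "dip": 0.09999999999999992}, {"x": [0.14942006550815898, 0.24133209036562578, 0.21657254925500274, 0.2089174309926935, 0.20020528093045745, 0.20282788459730652, 0.21574629593338862, 0.837565826985543, 0.809244802744444, 0.9136022323425229, 0.6991196508231566, 0.7968061585552237, 0.9108661173122145, 0.7252325524834013, 0.8177026474294437], "dip": 0.1815887322166253}, {"x": [0.214814, 0.186243, 0.200297, 0.800808, 0.807954, 0.797698], "dip": 0.23831843717035595}, {"x": [0.14511454588154593, 0.6741065748360536, 0.9921767009274504, 0.8130839708948975, 0.9859883633783706, 0.15544137373980182], "dip": 0.16341304868724713}, {"x": [0.0, 0.0, 0.0, 0.0, 0.0, 0.9308926037822387, 0.7222473464967749, 0.649275311761287, 0.9564287328028513, 0.5272247162461103, 0.5813011437898523], "dip": 0.15033902061352097}, {"x": [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.5332757929399834, 0.8514177912629562, 0.7880102477925608, 0.6087910533840003, 0.8286163314548478, 0.8775892277459701, 0.7193631477571527], "dip": 0.1519149780101752}, {"x": [0.8, 0.4, 0.1, 0.1, 1.0, 0.4, 0.5, 0.5, 0.9, 0.9, 0.6, 0.7, 0.6, 0.4], "dip": 0.07142857142857145}, {"x": [4.0, 6.0, 0.0, 4.0, 6.0, 4.0, 0.0, 0.0, 0.0, 1.0, 1.0, 3.0, 4.0, 6.0], "dip": 0.14285714285714285}, {"x": [0.996742, 0.580943, 0.658229, 0.119722, 0.701195, 0.903876, 0.939139, 0.67149], "dip": 0.12858424379201958}, {"x": [0.1, 0.2, 0.3, 0.5, 0.0, 0.5, 0.8, 0.4], "dip": 0.0625}, {"x": [0.845597, 0.158951, 0.593027, 0.202142], "dip": 0.15186959461034572}, {"x": [0.23660587783051032, 0.18298564711138637, 0.19334184561634857, 0.7372679023073214, 0.7474368688962996, 0.7647017992552076], "dip": 0.22581546666139907}, {"x": [0.1853244277516064, 0.17126358286225737, 0.2531826237554008, 0.28418080594769324, 0.10481912420686579, 0.20745899233045195, 0.8377170772469675, 0.8944281290710892, 0.7531430097209717, 0.7507644503136769, 0.8415453783581294, 0.7320367090240458], "dip": 0.1785089871192356}, {"x": [0.1, 0.6, 0.0, 0.6, 0.6, 0.7, 0.7, 0.8, 0.2], "dip": 0.11111111111111116}, {"x": [0.9598304389942929, 0.9831314342524605, 0.17957198375590344, 0.533766211516905, 0.6640561406332494, 0.5029329772295091, 0.4271354381097844, 0.03138358826131671], "dip": 0.1158716705256819}, {"x": [0.6883566092359521, 0.9769094886216131, 0.753476823079368, 0.41698050325464175, 0.29040793799862563, 0.29858383498220986, 0.9685649724563465], "dip": 0.13859919669236642}, {"x": [0.18777132836049848, 0.16346603260414042, 0.23773833835983124, 0.22384312816721608, 0.1733192466963911, 0.22395787069554762, 0.3045436102915166, 0.7601570441567659, 0.8071051695922119, 0.7845897073902348, 0.6585541531704792, 0.7649509212207687, 0.8274835803358215, 0.7982097349461409, 0.7928359626886222], "dip": 0.170284474451738}, {"x": [0.002499133392535602, 0.05182114527067805, 0.03408938914222526, 0.3832977133563924, 0.3387618068575101], "dip": 0.17312877543285904}, {"x": [0.0, 0.0, 0.0, 0.0, 0.0, 0.5778987141572097, 0.507097111515853, 0.7722243720833479, 0.9482281869374618, 0.7515363159461792, 0.737606344368136], "dip": 0.14924333871437456}, {"x": [0.0, 0.0, 0.0, 0.0, 0.8205731734008358, 0.8166511446080418, 0.6246478868234429, 0.8498860147505347, 0.8906204416765311], "dip": 0.1991517580806286}, {"x": [0.0, 0.0, 0.774556194728514, 0.6266050908914184], "dip": 0.20224649133141548}, {"x": [0.20540354621514167, 0.20823161255266384, 0.2594018637487138, 0.2301075956127441, 0.8098056354908142, 0.7563581135480462, 0.7599187372349435, 0.8549703492538827, 0.8679725572559004], "dip": 0.20044252053709025}, {"x": [1.0, 0.0, 0.0, 0.0, 2.0, 1.0, 0.0, 2.0], "dip": 0.125}, {"x": [0.9, 0.6, 0.7, 0.1, 0.3], "dip": 0.12000000000000002}, {"x": [0.0, 2.0, 2.0, 1.0, 1.0, 1.0, 1.0, 3.0, 1.0], "dip": 0.11111111111111116}, {"x": [2.0, 2.0, 0.0, 3.0, 2.0, 1.0, 3.0, 3.0], "dip": 0.1875}, {"x": [0.42449043380224993, 0.6709011683775186, 0.7605132529058005, 0.36076346029735074, 0.6005508941604725, 0.4723618776768521, 0.8024532343505165, 0.8430062127849087, 0.23710559634492645, 0.7489427939788521, 0.9134308685276604, 0.20638336466179397, 0.12890164815254224], "dip": 0.06272050888954867}, {"x": [2.0, 2.0, 0.0, 2.0, 3.0, 3.0, 1.0, 3.0, 1.0], "dip": 0.16666666666666663}, {"x": [0.0, 0.0, 0.0, 0.0, 0.0, 0.6912818520941673, 0.5634450173942358, 0.5251063971657874, 0.8118668592029283, 0.8598471266193226], "dip": 0.15267434783156122}, {"x": [0.8129270017919356, 0.2900238283040405, 0.23968643103465226, 0.14202510455320216, 0.04666533973874232, 0.6126766878265617, 0.7017456041112943, 0.1851681009269076, 0.5353319485592931, 0.23909964644298953, 0.3350422651788344, 0.5094333708389722, 0.33677791285380776], "dip": 0.07486041359084941}, {"x": [3.0, 3.0, 3.0, 0.0, 0.0, 2.0, 1.0, 3.0, 2.0, 2.0], "dip": 0.15000000000000002}, {"x": [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.8059046382474523, 0.5421853872269294, 0.642559326716057, 0.5829428214555494, 0.8754366732329373, 0.9348965236413493], "dip": 0.1449854003936069}, {"x": [0.429826, 0.593757, 0.53455, 0.202293, 0.775487, 0.384041], "dip": 0.10647162525696785}, {"x": [0.0, 0.0, 0.0, 0.0, 0.0, 0.5877019047439, 0.7521476271114822, 0.7643831242422048, 0.8454789442511415, 0.5468448152474434], "dip": 0.1616967574904527}, {"x": [0.43291, 0.41432, 0.553627, 0.496567, 0.207392], "dip": 0.10546484753597246}, {"x": [0.1, 0.5, 0.2, 0.9, 0.5], "dip": 0.15}, {"x": [1.0, 0.6, 0.1, 0.1, 0.7, 0.2, 0.3, 0.1, 0.7, 0.6], "dip": 0.14999999999999997}]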