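"participant_id","session_index","season","year","sex","age","maturity_offset","bone_age","bmi","radial_sos","tibial_sos","grip_strength","knee_extension","ntx_raw","creatinine","ntx","paqc","waeq","energy_intake","exclusion_flags"
"P001",1,"fall",2010,"female","10.420804821629492","-4.16435636749267069","9.6219214923283420","22.9025265860984106","3728.1374860550291","3495.2400948118830","12.236847473985730","104.510924191697399","3303.37058269141426","9.4169646488764158","350.789315438871881","-0.345258591457005437","63.0541563403894969","2165.700572054156055",""
"P001",2,"fall",2011,"female","10.130474445908217","-0.23972405110907946","12.7825344843726807","19.9602810237721329","3784.2319760148494","3701.3833762125423","19.861790799129331","143.999598675104636","2619.28901514217932","12.0297356621485854","217.734544524011426","0.058486730959582428","95.5570686183420719","1780.517799596176246",""
"P002",1,"fall",2010,"female","12.359173104514392","-2.03004846071656386","10.3360771968996339","15.2622533012795518","3851.5817106482264","3665.2640511871632","19.435072837975120","36.795204837796575","756.52071338003975","10.5523398199112322","71.692224311480118","-0.130747869546656209","46.3435230827357287","1834.021436010656316",""
"P002",2,"fall",2011,"female","10.779791879847476","-0.73554191963553128","8.0462882716438315","18.0789219649945458","3959.5207375898185","3673.7750348960158","11.752159184368123","28.442397908225260","4810.25876785440687","10.4440956592789362","460.572071032381587","0.072119153403395142","83.0176168217201962","2074.464652670862506",""
"P003",1,"spring",2010,"male","10.374489639387434","-0.42538329420269660","12.1273891678599046","17.9909219229127828","3943.8829618691566","3795.4394565030152","14.501051403835351","78.894346608194752","3532.79193554647463","7.8836739036113945","448.114924429859400","0.608653626977615270","69.4106720163738515","684.855367116544357",""
"P003",2,"spring",2011,"male","10.997982782887625","0.13113103535860515","12.8543605230070597","20.0817446064958993","3906.1916416383642","3762.9500044626116","18.435968821987466","113.443490223223762","2839.89362762741484","10.0719868564171637","281.959624065437879","-0.171277116821055425","72.1758393336028519","666.715879790256395",""
"P004",1,"fall",2011,"male","15.485289680028183","1.09119965125133023","14.0787101746963614","5.7780455560865249","4003.1283379579841","3844.4512810671577","21.102446807924270","151.275620744707965","5196.43188849181479","9.7469610998438334","533.133541342959916","0.156456953033012658","31.0751156998381859","1826.319234785496974",""
"P004",2,"fall",2012,"male","13.448510331494775","2.80893939476363919","15.6157451502635123","5.9434297342002829","3866.5054399105984","3820.0106884918787","25.232976737126751","168.918321500924549","1769.97898662416924","8.3003434431787859","213.241656654428709","0.089075436690308388","4.6325590320167436","1304.048875319141189",""
"P005",1,"fall",2011,"female","14.019916264017086","1.59622594187305955","12.6229371902325731","22.8477076953866636","3899.2449225907199","3734.6249350618982","34.158398291034352","185.306673462308140","314.21741337931940","11.2629226176587469","27.898390501828430","-0.464462097218955705","40.8927131315100070","1686.281806145593919",""
"P005",2,"fall",2012,"female","18.136475583541305","2.49690669412912003","14.4424404869512717","28.0885080117244996","3859.8043269204427","3658.6203217210082","33.756622632657923","215.228896569288054","4006.58614396771918","8.6646947086441717","462.403613594212743","-0.292155349197923186","65.6548026928305575","-27.092832052255289",""
"P006",1,"spring",2012,"male","10.214650456904270","-2.46508291911163813","5.2805598625792705","19.6911295806860451","3777.5279021498473","3770.2734173768108","10.258107127682324","88.558919407725924","8739.93856181918454","9.5998276149626793","910.426615181793750","0.092161575311891009","167.8211822940176603","2493.448160957999335",""
"P006",2,"spring",2013,"male","14.645880107688274","2.51196986529710520","11.3546755240638380","23.4037438009598731","3843.3299057830841","3911.0293982762701","20.355340813874136","165.945505830099307","4977.17863891713569","13.8751358286542352","358.712065984861624","0.232415816236497819","155.3578543971807449","1755.647552271248060",""
"P007",1,"spring",2011,"male","11.632335344159454","-1.83455103530202646","11.2729973133964680","19.5107598388559715","3806.2406073769189","3696.7440453194722","27.396435083891049","33.295189132441834","5061.60477259762956","12.6735712702898464","399.382673174636238","0.257463712527489064","85.6480790029413868","2383.381381298098404",""
"P007",2,"spring",2012,"male","15.036846783241584","-2.03192376633266170","9.9391878194787786","18.6496163850119174","3714.4340977055449","3735.7368017982708","19.821730237991591","85.819902543909265","6524.69352873567186","8.8703596905899271","735.561325168962185","-0.198703047359323121","119.1668462995782818","2162.587980188567599",""
"P008",1,"spring",2010,"female","11.048285590767723","-4.13991545806325334","8.4361824992788730","22.1531767980146945","3817.3900433536182","3494.7450800900742","17.641153979894721","-30.580233158669330","2893.47166251749923","10.0701911819061554","287.330360491706472","0.323488257553294245","26.3775656078006051","2090.966172363293936",""
"P008",2,"spring",2011,"female","11.663804627604277","-0.49019579835923083","12.7672520857969509","23.6555435961239837","3821.1767759681079","3652.0983648879346","22.362361399542014","74.418529908445365","3616.29267600623371","11.7810817854724359","306.957607277251896","-0.332548999252145094","71.1716717798410343","1539.465828968854339",""
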