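name,state,year,source,diapause,cry3bb1_response,pool_chromosomes,pi
Jones,IA,2011,Field,TRUE,NA,10,0.0064
Plainview,MN,2011,Field,TRUE,NA,10,0.0063
Gayville,SD,2011,Field,TRUE,medium,10,0.0067
Humphrey,NE,2011,Field,TRUE,high,10,0.0061
Sherman 2,CO,2011,Field,TRUE,NA,10,0.0063
North Mankato,MN,2011,Field,TRUE,medium,10,0.0065
Maynard,IA,2011,Field,TRUE,NA,10,0.0064
Kit Carson 2,CO,2011,Field,TRUE,high,10,0.0063
Onslow,IA,2011,Field,TRUE,low,10,0.0066
Kit Carson 3,CO,2011,Field,TRUE,medium,10,0.0065
Shell rock,IA,2011,Field,TRUE,medium,10,0.0063
Trent,SD,2011,Field,TRUE,low,10,0.0063
Adams,IN,2012,Field,TRUE,high,10,0.0058
Fillmore,MN,2012,Field,TRUE,NA,10,0.0057
Colfax,NE,2012,Field,TRUE,NA,10,0.0059
Moody,SD,2012,Field,TRUE,low,10,0.0057
Sherman 1,KS,2012,Field,TRUE,medium,10,0.0058
Hansel,IA,2012,Field,TRUE,NA,10,0.0059
Kit Carson 1,CO,2012,Field,TRUE,NA,10,0.0059
Knox,IL,2012,Field,TRUE,medium,10,0.0057
Hopkinton,IA,2009,Lab,FALSE,low,10,0.0056
Brookings (random mated),SD,NA,Lab,FALSE,high,10,0.0055
Brookings (inbred),SD,NA,Lab,FALSE,high,10,0.005
Seneca resistant,KS,2005,Lab,FALSE,low,10,0.0056
Seneca susceptible,KS,2005,Lab,FALSE,NA,10,0.0056
Waterman,IL,NA,Lab,TRUE,high,10,0.0063
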