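pair_id,taxon_id,status,trait,value,unit,source_id,independent
P01,P01_listed,listed,litter_clutch,4.835260061244996,count,SRC_P01_listed_litter_clutch_01,TRUE
P01,P01_listed,listed,litter_clutch,6.975651347224927,count,SRC_P01_listed_litter_clutch_02,TRUE
P01,P01_listed,listed,litter_clutch,4.750163276305729,count,SRC_P01_listed_litter_clutch_03,TRUE
P01,P01_listed,listed,litter_clutch,2.9517665217550615,count,SRC_P01_listed_litter_clutch_04,TRUE
P01,P01_listed,listed,litter_clutch,4.708340035837658,count,SRC_P01_listed_litter_clutch_05,TRUE
P01,P01_listed,listed,home_range,13.30479051125312,km2,SRC_P01_listed_home_range_01,TRUE
P01,P01_listed,listed,home_range,14.784251618147778,km2,SRC_P01_listed_home_range_02,TRUE
P01,P01_listed,listed,home_range,9.512550859841868,km2,SRC_P01_listed_home_range_03,TRUE
P01,P01_listed,listed,home_range,9.995693399558892,km2,SRC_P01_listed_home_range_04,TRUE
P01,P01_listed,listed,home_range,11.782207811054384,km2,SRC_P01_listed_home_range_05,TRUE
P01,P01_listed,listed,dispersal,4.648628569190189,km,SRC_P01_listed_dispersal_01,TRUE
P01,P01_listed,listed,dispersal,17.221728607191974,km,SRC_P01_listed_dispersal_02,TRUE
P01,P01_listed,listed,dispersal,6.755894793277929,km,SRC_P01_listed_dispersal_03,TRUE
P01,P01_listed,listed,dispersal,9.514719785568225,km,SRC_P01_listed_dispersal_04,TRUE
P01,P01_listed,listed,dispersal,19.97514321963838,km,SRC_P01_listed_dispersal_05,TRUE
P01,P01_listed,listed,survival,0.7818949391468027,proportion,SRC_P01_listed_survival_01,TRUE
P01,P01_listed,listed,survival,0.7312870611661801,proportion,SRC_P01_listed_survival_02,FALSE
P01,P01_listed,listed,survival,0.6425011484956139,proportion,SRC_P01_listed_survival_03,TRUE
P01,P01_listed,listed,survival,0.6727126110561717,proportion,SRC_P01_listed_survival_04,FALSE
P01,P01_listed,listed,survival,0.7425873880487274,proportion,SRC_P01_listed_survival_05,TRUE
P01,P01_nonlisted,nonlisted,litter_clutch,4.776109134627538,count,SRC_P01_nonlisted_litter_clutch_01,TRUE
P01,P01_nonlisted,nonlisted,litter_clutch,7.025817059065169,count,SRC_P01_nonlisted_litter_clutch_02,FALSE
P01,P01_nonlisted,nonlisted,litter_clutch,3.810108137796958,count,SRC_P01_nonlisted_litter_clutch_03,TRUE
P01,P01_nonlisted,nonlisted,litter_clutch,10.315291672277166,count,SRC_P01_nonlisted_litter_clutch_04,TRUE
P01,P01_nonlisted,nonlisted,litter_clutch,3.497423654822946,count,SRC_P01_nonlisted_litter_clutch_05,TRUE
P01,P01_nonlisted,nonlisted,home_range,6.254768509711482,km2,SRC_P01_nonlisted_home_range_01,FALSE
P01,P01_nonlisted,nonlisted,home_range,4.076627035454675,km2,SRC_P01_nonlisted_home_range_02,TRUE
P01,P01_nonlisted,nonlisted,home_range,3.2681472057450964,km2,SRC_P01_nonlisted_home_range_03,TRUE
P01,P01_nonlisted,nonlisted,home_range,5.621343910242,km2,SRC_P01_nonlisted_home_range_04,TRUE
P01,P01_nonlisted,nonlisted,home_range,3.0302411561187004,km2,SRC_P01_nonlisted_home_range_05,TRUE
P01,P01_nonlisted,nonlisted,dispersal,20.253350040543197,km,SRC_P01_nonlisted_dispersal_01,TRUE
P01,P01_nonlisted,nonlisted,dispersal,20.680193459593813,km,SRC_P01_nonlisted_dispersal_02,TRUE
P01,P01_nonlisted,nonlisted,dispersal,22.983045103331886,km,SRC_P01_nonlisted_dispersal_03,FALSE
P01,P01_nonlisted,nonlisted,dispersal,24.556001970060496,km,SRC_P01_nonlisted_dispersal_04,TRUE
P01,P01_nonlisted,nonlisted,dispersal,11.885074224725313,km,SRC_P01_nonlisted_dispersal_05,TRUE
P01,P01_nonlisted,nonlisted,survival,0.714127583640701,proportion,SRC_P01_nonlisted_survival_01,TRUE
P01,P01_nonlisted,nonlisted,survival,0.6239871663208122,proportion,SRC_P01_nonlisted_survival_02,TRUE
P01,P01_nonlisted,nonlisted,survival,0.8081993145995923,proportion,SRC_P01_nonlisted_survival_03,TRUE
P01,P01_nonlisted,nonlisted,survival,0.7083638590284599,proportion,SRC_P01_nonlisted_survival_04,TRUE
P01,P01_nonlisted,nonlisted,survival,0.7478298325215538,proportion,SRC_P01_nonlisted_survival_05,TRUE
P02,P02_listed,listed,litter_clutch,6.532002036348739,count,SRC_P02_listed_litter_clutch_01,TRUE
P02,P02_listed,listed,litter_clutch,5.7471968244005245,count,SRC_P02_listed_litter_clutch_02,TRUE
P02,P02_listed,listed,litter_clutch,5.482681836127871,count,SRC_P02_listed_litter_clutch_03,TRUE
P02,P02_listed,listed,litter_clutch,3.132961826973984,count,SRC_P02_listed_litter_clutch_04,TRUE
P02,P02_listed,listed,litter_clutch,4.549479719475812,count,SRC_P02_listed_litter_clutch_05,TRUE
P02,P02_listed,listed,home_range,13.490462549049383,km2,SRC_P02_listed_home_range_01,TRUE
P02,P02_listed,listed,home_range,10.452889032552244,km2,SRC_P02_listed_home_range_02,TRUE
P02,P02_listed,listed,home_range,13.392231886201348,km2,SRC_P02_listed_home_range_03,TRUE
P02,P02_listed,listed,home_range,11.485558804590305,km2,SRC_P02_listed_home_range_04,TRUE
P02,P02_listed,listed,home_range,6.890235842906928,km2,SRC_P02_listed_home_range_05,TRUE
P02,P02_listed,listed,dispersal,4.7858275216462856,km,SRC_P02_listed_dispersal_01,FALSE
P02,P02_listed,listed,dispersal,6.003348716756729,km,SRC_P02_listed_dispersal_02,TRUE
P02,P02_listed,listed,dispersal,7.508929887622779,km,SRC_P02_listed_dispersal_03,TRUE
P02,P02_listed,listed,dispersal,7.6268821927886155,km,SRC_P02_listed_dispersal_04,FALSE
P02,P02_listed,listed,dispersal,7.212326053104241,km,SRC_P02_listed_dispersal_05,TRUE
P02,P02_listed,listed,survival,0.699736264869164,proportion,SRC_P02_listed_survival_01,FALSE
P02,P02_listed,listed,survival,0.4909462409789202,proportion,SRC_P02_listed_survival_02,FALSE
P02,P02_listed,listed,survival,0.37935801257812096,proportion,SRC_P02_listed_survival_03,TRUE
P02,P02_listed,listed,survival,0.5123907985164645,proportion,SRC_P02_listed_survival_04,TRUE
P02,P02_listed,listed,survival,0.5563519096168745,proportion,SRC_P02_listed_survival_05,TRUE
P02,P02_nonlisted,nonlisted,litter_clutch,8.78182791662877,count,SRC_P02_nonlisted_litter_clutch_01,TRUE
P02,P02_nonlisted,nonlisted,litter_clutch,4.170426983503681,count,SRC_P02_nonlisted_litter_clutch_02,FALSE
P02,P02_nonlisted,nonlisted,litter_clutch,4.662994521794663,count,SRC_P02_nonlisted_litter_clutch_03,TRUE
P02,P02_nonlisted,nonlisted,litter_clutch,3.7080497961266192,count,SRC_P02_nonlisted_litter_clutch_04,TRUE
P02,P02_nonlisted,nonlisted,litter_clutch,3.6117366776844664,count,SRC_P02_nonlisted_litter_clutch_05,TRUE
P02,P02_nonlisted,nonlisted,home_range,2.0483894875531856,km2,SRC_P02_nonlisted_home_range_01,TRUE
P02,P02_nonlisted,nonlisted,home_range,3.821502387679259,km2,SRC_P02_nonlisted_home_range_02,TRUE
P02,P02_nonlisted,nonlisted,home_range,6.534486080294127,km2,SRC_P02_nonlisted_home_range_03,TRUE
P02,P02_nonlisted,nonlisted,home_range,3.8083057811239183,km2,SRC_P02_nonlisted_home_range_04,TRUE
P02,P02_nonlisted,nonlisted,home_range,7.817680907806752,km2,SRC_P02_nonlisted_home_range_05,TRUE
P02,P02_nonlisted,nonlisted,dispersal,9.400826488099405,km,SRC_P02_nonlisted_dispersal_01,FALSE
P02,P02_nonlisted,nonlisted,dispersal,9.655594057966018,km,SRC_P02_nonlisted_dispersal_02,FALSE
P02,P02_nonlisted,nonlisted,dispersal,8.238583831710052,km,SRC_P02_nonlisted_dispersal_03,TRUE
P02,P02_nonlisted,nonlisted,dispersal,20.402472823716447,km,SRC_P02_nonlisted_dispersal_04,TRUE
P02,P02_nonlisted,nonlisted,dispersal,13.104829863331718,km,SRC_P02_nonlisted_dispersal_05,TRUE
P02,P02_nonlisted,nonlisted,survival,0.49850895157359076,proportion,SRC_P02_nonlisted_survival_01,TRUE
P02,P02_nonlisted,nonlisted,survival,0.5902815133379797,proportion,SRC_P02_nonlisted_survival_02,FALSE
P02,P02_nonlisted,nonlisted,survival,0.588293181159754,proportion,SRC_P02_nonlisted_survival_03,TRUE
P02,P02_nonlisted,nonlisted,survival,0.6946463210776149,proportion,SRC_P02_nonlisted_survival_04,TRUE
P02,P02_nonlisted,nonlisted,survival,0.5045614385165339,proportion,SRC_P02_nonlisted_survival_05,TRUE
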