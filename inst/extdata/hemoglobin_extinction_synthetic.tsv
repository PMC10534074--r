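# SYNTHETIC hemoglobin molar extinction table (do not use for clinical work)
# Reconstructed by log10 spline through widely quoted anchor values of the
# canonical oxy/deoxy-hemoglobin compilation; see data-raw/make_extinction_table.R.
# columns: wavelength_nm  eps_HbO2  eps_Hb   [L mol^-1 cm^-1, base-10]
450	62816	52000
452	58530.81	49595.61
454	54560.08	47241.76
456	50900	44884.31
458	47543.26	42480.69
460	44480	40000
462	41699.34	37453.64
464	39192	34969.84
466	36948.14	32674.58
468	34957.28	30661.57
470	33209	29000
472	31687.58	27719.14
474	30356.81	26750.28
476	29180.64	26015.99
478	28128.25	25451.42
480	27173	25000
482	26293.96	24612.52
484	25481.79	24251.23
486	24730.35	23882.63
488	24034.09	23475.27
490	23388	23000
492	22788.38	22448.33
494	22235.22	21882.25
496	21729.28	21374.96
498	21271.3	20993.16
500	20862	20800
502	20505.96	20839.36
504	20222.55	21078.48
506	20034.24	21468.2
508	19963.69	21959.43
510	20035	22500
512	20278.64	23045.65
514	20744.08	23600.08
516	21494.68	24180.79
518	22611.26	24807.02
520	24202	25500
522	26379.69	26280.5
524	29138.98	27160
526	32414.75	28148.48
528	36087.16	29257.43
530	39956	30500
532	43751.78	31889.57
534	47239.76	33434.07
536	50178.69	35140.18
538	52315.67	37014.8
540	53412.92	39064.83
542	53280	41296.97
544	51867.09	43717.42
546	49448.93	46325.79
548	46386.55	48977.32
550	43016	51343.63
552	39653.6	53034.52
554	36667.22	53637.97
556	34349.71	52799.65
558	32924.94	50665.6
560	32613	47826.88
562	33602.32	44833.6
564	35766.51	42131.16
566	38928.76	40052.52
568	42885.36	38590.5
570	47322.48	37479.3
572	51537.74	36480.62
574	54345.81	35382.76
576	54424	34000
578	51011.14	32232.26
580	44948.82	30204.01
582	37578.9	28074.1
584	30084.07	25972.85
586	23275	24000
588	17562.76	22214.54
590	13044.16	20609.19
592	9623.35	19164.43
594	7116.86	17863.1
596	5324.39	16690.05
598	4066.63	15631.95
600	3200	14677
602	2611.33	13813.16
604	2201.6	13023.78
606	1905.57	12293.48
608	1682.56	11609.46
610	1506	10961.1
612	1358.91	10339.67
614	1233.4	9738.11
616	1124.49	9151.22
618	1028.35	8581.93
620	942	8039.01
622	863.43	7529.35
624	792.11	7057.88
626	727.78	6627.95
628	670.1	6241.61
630	618.69	5900
632	573.15	5602.08
634	533.07	5340.76
636	498.09	5108.68
638	467.84	4899.59
640	442	4708.15
642	420.2	4529.75
644	401.81	4360.39
646	386.2	4196.69
648	372.87	4037.64
650	361.39	3884.2
652	351.38	3737.26
654	342.51	3597.54
656	334.5	3465.62
658	327.08	3341.98
660	320	3227
662	313.11	3120.71
664	306.44	3022.21
666	300.12	2930.42
668	294.21	2844.4
670	288.81	2763.3
672	283.99	2686.35
674	279.82	2612.85
676	276.39	2542.16
678	273.76	2473.72
680	272	2407
682	271.16	2341.59
684	271.17	2277.31
686	271.93	2214.08
688	273.33	2151.78
690	275.28	2090.35
692	277.69	2029.72
694	280.46	1969.81
696	283.51	1910.58
698	286.72	1851.99
700	290	1794
702	293.27	1736.71
704	296.56	1680.73
706	299.96	1626.7
708	303.55	1575.17
710	307.4	1526.64
712	311.61	1481.51
714	316.28	1440.16
716	321.49	1402.89
718	327.36	1369.84
720	334	1340.98
722	341.52	1316.3
724	349.92	1295.81
726	359.16	1279.55
728	369.21	1267.58
730	380.05	1260
732	391.63	1256.91
734	403.9	1258.39
736	416.8	1264.52
738	430.28	1275.45
740	444.25	1291.38
742	458.63	1312.58
744	473.32	1339.38
746	488.2	1372.13
748	503.14	1410.06
750	518	1451.1
752	532.64	1492.85
754	547.03	1532.64
756	561.15	1567.55
758	575	1594.41
760	588.56	1610
762	601.85	1611.9
764	614.86	1600.86
766	627.59	1578.61
768	640.06	1547.1
770	652.27	1508.29
772	664.23	1464.16
774	675.96	1416.56
776	687.49	1367.19
778	698.83	1317.38
780	710	1268.11
782	721.03	1220.2
784	731.94	1174.38
786	742.72	1131.25
788	753.4	1091.31
790	763.98	1055
792	774.49	1022.54
794	784.92	993.59
796	795.31	967.71
798	805.66	944.53
800	816	923.71
802	826.34	904.93
804	836.68	887.92
806	847.01	872.43
808	857.32	858.23
810	867.62	845.15
812	877.89	833.02
814	888.12	821.69
816	898.32	811
818	908.47	800.81
820	918.56	791
822	928.59	781.46
824	938.55	772.2
826	948.43	763.26
828	958.23	754.66
830	967.93	746.44
832	977.53	738.62
834	987.03	731.24
836	996.4	724.32
838	1005.65	717.89
840	1014.76	711.97
842	1023.73	706.59
844	1032.55	701.78
846	1041.21	697.56
848	1049.69	693.96
850	1058	691
852	1066.12	688.72
854	1074.05	687.11
856	1081.79	686.18
858	1089.33	685.93
860	1096.67	686.38
862	1103.8	687.52
864	1110.73	689.38
866	1117.45	691.96
868	1123.96	695.28
870	1130.25	699.37
872	1136.33	704.23
874	1142.19	709.89
876	1147.84	716.39
878	1153.26	723.75
880	1158.46	732
882	1163.43	741.14
884	1168.18	750.97
886	1172.7	761.25
888	1177	771.71
890	1181.07	782.09
892	1184.91	792.08
894	1188.53	801.39
896	1191.91	809.7
898	1195.07	816.68
900	1198	822
902	1200.7	825.41
904	1203.18	826.95
906	1205.43	826.75
908	1207.47	824.94
910	1209.3	821.68
912	1210.91	817.12
914	1212.32	811.41
916	1213.53	804.71
918	1214.54	797.19
920	1215.36	789
922	1215.99	780.28
924	1216.43	771.14
926	1216.7	761.66
928	1216.8	751.94
930	1216.72	742.07
932	1216.49	732.11
934	1216.09	722.16
936	1215.54	712.27
938	1214.84	702.53
940	1214	693
942	1213.02	683.72
944	1211.89	674.7
946	1210.59	665.92
948	1209.12	657.36
950	1207.46	649.01
952	1205.59	640.87
954	1203.52	632.9
956	1201.22	625.11
958	1198.68	617.48
960	1195.89	610
962	1192.85	602.67
964	1189.53	595.5
966	1185.93	588.51
968	1182.05	581.74
970	1177.86	575.2
972	1173.35	568.92
974	1168.53	562.9
976	1163.38	557.17
978	1157.92	551.73
980	1152.17	546.55
982	1146.17	541.61
984	1139.96	536.88
986	1133.55	532.33
988	1126.99	527.95
990	1120.3	523.72
992	1113.52	519.6
994	1106.67	515.6
996	1099.78	511.67
998	1092.88	507.81
1000	1086	504
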